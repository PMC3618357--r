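#' Diploid multi-allelic genotype matrix
#'
#' The universal data container of the package: `S` individuals typed at `L`
#' loci, each call an unordered pair of allele codes (small positive
#' integers).  A call is either fully typed or fully missing (`NA` in both
#' slots); per-allele missingness does not exist for this marker type.
#'
#' Internally the calls are stored as two integer matrices `a1` and `a2`
#' (individuals x loci) normalised so that `a1 <= a2` element-wise, which
#' makes genotype comparisons order-free.
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   codes of every call; `NA` in both marks a missing call.
#' @param individual_ids optional character vector of row labels.
#' @param locus_names optional character vector of locus labels.
#' @param pop optional vector of population labels (one per individual),
#'   retained as metadata (e.g. Genepop blocks).
#' @return An object of class `genotype_matrix`.
#' @examples
#' gm <- genotype_matrix(matrix(c(1L, 1L, 2L, 1L), 2, 2),
#'                       matrix(c(1L, 2L, 2L, 3L), 2, 2))
#' n_individuals(gm)
#' @export
genotype_matrix <- function(a1, a2, individual_ids = NULL, locus_names = NULL,
                            pop = NULL) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices 'a1' and 'a2' must have identical dimensions")
  if (any(is.na(a1) != is.na(a2)))
    stop("half-missing calls found: a call must be fully typed or fully missing")
  if (any(a1 < 1L, na.rm = TRUE) || any(a2 < 1L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  # unordered pair: store as (min, max)
  sw <- which(!is.na(a1) & a1 > a2)
  lo <- a1
  lo[sw] <- a2[sw]
  hi <- a2
  hi[sw] <- a1[sw]
  n <- nrow(lo)
  L <- ncol(lo)
  if (is.null(individual_ids)) individual_ids <- sprintf("ind_%d", seq_len(n))
  if (is.null(locus_names)) locus_names <- sprintf("locus_%d", seq_len(L))
  if (length(individual_ids) != n) stop("individual_ids length mismatch")
  if (length(locus_names) != L) stop("locus_names length mismatch")
  if (anyDuplicated(locus_names)) stop("locus_names must be unique")
  if (!is.null(pop) && length(pop) != n) stop("pop length mismatch")
  dimnames(lo) <- dimnames(hi) <- NULL
  structure(list(a1 = lo, a2 = hi,
                 individual_ids = as.character(individual_ids),
                 locus_names = as.character(locus_names),
                 pop = pop),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`.
#' @export
n_individuals <- function(gm) nrow(gm$a1)

#' @rdname genotype_matrix
#' @export
n_loci <- function(gm) ncol(gm$a1)

#' @export
print.genotype_matrix <- function(x, ...) {
  typed <- !is.na(x$a1)
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% calls typed)\n",
              n_individuals(x), n_loci(x), 100 * mean(typed)))
  cat("loci:", paste(x$locus_names, collapse = ", "), "\n")
  invisible(x)
}

#' Subset individuals of a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i individual (row) index.
#' @param ... ignored.
#' @return A `genotype_matrix` with the selected individuals.
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  genotype_matrix(x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                  individual_ids = x$individual_ids[i],
                  locus_names = x$locus_names,
                  pop = if (!is.null(x$pop)) x$pop[i])
}

# locus index from name or position, with informative error
locus_index <- function(gm, locus) {
  if (is.character(locus)) {
    idx <- match(locus, gm$locus_names)
    if (is.na(idx)) stop("unknown locus: ", locus)
    idx
  } else {
    locus <- as.integer(locus)
    if (locus < 1L || locus > n_loci(gm)) stop("locus index out of range: ", locus)
    locus
  }
}

# run code with a locally-seeded RNG, restoring the caller's RNG state;
# seed = NULL leaves the RNG alone (stream continues)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Per-locus allele frequencies
#'
#' Computes, for every locus, the relative frequency of each observed allele
#' among typed calls (count of the allele divided by twice the number of
#' individuals scored at the locus) together with the per-locus sample size.
#'
#' @param gm a [genotype_matrix()].
#' @return An object of class `afreq_table`: a list with elements `loci`
#'   (locus names), `freqs` (per locus, a named numeric vector of allele
#'   frequencies; names are allele codes), `counts` (the corresponding allele
#'   copy counts) and `n_typed` (individuals scored per locus).
#' @examples
#' gm <- genotype_matrix(matrix(c(1L, 1L, 2L), 3, 1),
#'                       matrix(c(1L, 2L, 2L), 3, 1))
#' allele_frequencies(gm)
#' @export
allele_frequencies <- function(gm) {
  L <- n_loci(gm)
  freqs <- vector("list", L)
  counts <- vector("list", L)
  n_typed <- integer(L)
  for (l in seq_len(L)) {
    alleles <- c(gm$a1[, l], gm$a2[, l])
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0L)
      stop("locus '", gm$locus_names[l], "' has no typed individuals")
    tab <- table(alleles)
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    counts[[l]] <- cnt
    freqs[[l]] <- cnt / sum(cnt)
    n_typed[l] <- length(alleles) %/% 2L
  }
  names(freqs) <- names(counts) <- gm$locus_names
  afreq_table(gm$locus_names, freqs, n_typed, counts)
}

#' Construct an allele-frequency table
#'
#' @param loci character vector of locus names.
#' @param freqs list (one element per locus) of named numeric frequency
#'   vectors; names are allele codes and each vector must sum to 1.
#' @param n_typed optional integer vector of individuals scored per locus.
#' @param counts optional list of allele copy counts matching `freqs`.
#' @return An `afreq_table`.
#' @export
afreq_table <- function(loci, freqs, n_typed = NULL, counts = NULL) {
  stopifnot(length(loci) == length(freqs))
  for (l in seq_along(freqs)) {
    f <- freqs[[l]]
    if (length(f) < 1L) stop("locus '", loci[l], "' has no alleles")
    if (any(f <= 0) || any(f > 1))
      stop("locus '", loci[l], "': frequencies must lie in (0, 1]")
    if (abs(sum(f) - 1) > 1e-12)
      stop("locus '", loci[l], "': frequencies must sum to 1")
    if (is.null(names(f))) names(freqs[[l]]) <- seq_along(f)
  }
  structure(list(loci = as.character(loci), freqs = freqs,
                 n_typed = n_typed, counts = counts),
            class = "afreq_table")
}

#' @export
print.afreq_table <- function(x, ...) {
  na <- vapply(x$freqs, length, 1L)
  cat(sprintf("afreq_table: %d loci, %d alleles total\n", length(x$loci), sum(na)))
  for (l in seq_along(x$loci))
    cat(sprintf("  %-8s Na=%2d max=%.3f\n", x$loci[l], na[l], max(x$freqs[[l]])))
  invisible(x)
}

#' @export
as.data.frame.afreq_table <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$loci), function(l) {
    f <- x$freqs[[l]]
    data.frame(locus = x$loci[l], allele = names(f), freq = as.numeric(f),
               n_typed = if (is.null(x$n_typed)) NA_integer_ else x$n_typed[l],
               row.names = NULL)
  }))
}
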