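#' Allele-dosage indicator table
#'
#' Builds the individuals x alleles dosage table used by the
#' correspondence analysis: one column per (locus, allele) combination
#' observed in the data, entries 0/1/2 copies carried by the individual,
#' zeros for missing loci.  All-zero columns (alleles absent from the
#' current row set) are dropped.
#'
#' @param gm a [genotype_matrix()] with >= 2 individuals and >= 2 loci;
#'   every individual must be typed at at least one locus.
#' @return A numeric matrix with column names `locus.allele`.
#' @export
build_indicator <- function(gm) {
  n <- n_individuals(gm)
  L <- n_loci(gm)
  if (n < 2L || L < 2L) stop("need at least 2 individuals and 2 loci")
  if (any(rowSums(!is.na(gm$a1)) == 0L))
    stop("an individual with all loci missing cannot be placed by CA")
  cols <- list()
  for (l in seq_len(L)) {
    v1 <- gm$a1[, l]
    v2 <- gm$a2[, l]
    u <- sort(unique(c(v1[!is.na(v1)], v2[!is.na(v2)])))
    if (length(u) == 0L) next
    Y <- matrix(0, n, length(u))
    typed <- which(!is.na(v1))
    i1 <- cbind(typed, match(v1[typed], u))
    i2 <- cbind(typed, match(v2[typed], u))
    Y[i1] <- Y[i1] + 1
    Y[i2] <- Y[i2] + 1
    colnames(Y) <- paste(gm$locus_names[l], u, sep = ".")
    cols[[length(cols) + 1L]] <- Y
  }
  X <- do.call(cbind, cols)
  X[, colSums(X) > 0, drop = FALSE]
}

#' Correspondence analysis of a dosage table
#'
#' Classical CA: the table is scaled to a correspondence matrix, centred by
#' the outer product of row and column masses, standardised by inverse
#' square-root masses and decomposed by SVD.  Returns the row *principal*
#' coordinates on the first two axes (left singular vectors scaled by the
#' singular values and inverse square-root row masses), with each axis'
#' sign normalised so that its largest-magnitude column loading is
#' positive.
#'
#' @param x a dosage matrix from [build_indicator()] (rows = individuals).
#' @return A list: `coords` (n x 2 matrix of PC1/PC2 row principal
#'   coordinates), `sv` (first two singular values), `rank_deficient`
#'   (`TRUE` when no second axis exists, in which case PC2 is zero).
#' @export
ca_axes <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 rows")
  total <- sum(x)
  if (total <= 0) stop("indicator table is empty")
  P <- x / total
  r <- rowSums(P)
  cm <- colSums(P)
  if (any(r <= 0)) stop("zero row mass: individual with no typed alleles")
  S <- (P - outer(r, cm)) / sqrt(outer(r, cm))
  k <- min(dim(S))
  dec <- svd(S, nu = min(2L, k), nv = min(2L, k))
  sv <- dec$d[seq_len(min(2L, k))]
  tol <- max(dim(S)) * max(dec$d) * .Machine$double.eps
  coords <- matrix(0, nrow(x), 2L,
                   dimnames = list(rownames(x), c("PC1", "PC2")))
  rank_deficient <- FALSE
  for (a in 1:2) {
    if (a > length(sv) || sv[a] <= tol) {
      rank_deficient <- TRUE
      next
    }
    u <- dec$u[, a]
    v <- dec$v[, a]
    if (v[which.max(abs(v))] < 0) {
      u <- -u
      v <- -v
    }
    coords[, a] <- u * sv[a] / sqrt(r)
  }
  list(coords = coords, sv = sv, rank_deficient = rank_deficient)
}

#' Flag outlier individuals from CA coordinates
#'
#' An individual is an outlier when its distance from the origin of the
#' first two CA axes exceeds the threshold; distance is `|PC1| + |PC2|`
#' by default (absolute values, so the rule is invariant to the arbitrary
#' sign of each axis), with an L2 option.
#'
#' @param coords an n x 2 coordinate matrix (or the list from [ca_axes()]).
#' @param threshold outlier distance threshold (default 2).
#' @param norm `"l1"` (default) or `"l2"`.
#' @return Integer vector of flagged row indices (possibly empty).
#' @export
flag_outliers <- function(coords, threshold = 2, norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  if (is.list(coords)) coords <- coords$coords
  d <- switch(norm,
              l1 = abs(coords[, 1]) + abs(coords[, 2]),
              l2 = sqrt(coords[, 1]^2 + coords[, 2]^2))
  which(d > threshold)
}

#' Iterative CA outlier-genotype removal
#'
#' Repeatedly runs the correspondence analysis on the retained genotypes,
#' flags individuals beyond the coordinate threshold, removes them, and
#' rebuilds the allele columns from the survivors -- until an iteration
#' removes nobody or `max_iter` is reached.  Removal is permanent across
#' iterations.  This screens field samples for genotypes unlikely to come
#' from the focal breeding population (non-target species, immigrants from
#' diverged populations) before LD-based Ne estimation.
#'
#' @param gm a [genotype_matrix()].
#' @param threshold CA coordinate threshold (default 2).
#' @param max_iter maximum iterations (default 10).
#' @param norm distance norm passed to [flag_outliers()].
#' @return A list of class `ca_report`: `genotypes` (cleaned matrix),
#'   `removed` (original row indices removed, in removal order),
#'   `log` (per-iteration data frame: iteration, n_removed, n_retained),
#'   `removed_by_iteration` (list of original-index vectors),
#'   `iterations`, and `coords` (final-iteration coordinates of the
#'   retained individuals).
#' @export
iterative_clean <- function(gm, threshold = 2, max_iter = 10L,
                            norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  keep <- seq_len(n_individuals(gm))
  cur <- gm
  removed_by_iter <- list()
  log_rows <- list()
  coords <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ca <- ca_axes(build_indicator(cur))
    coords <- ca$coords
    out <- flag_outliers(ca$coords, threshold, norm)
    log_rows[[it]] <- data.frame(iteration = it, n_removed = length(out),
                                 n_retained = length(keep) - length(out))
    if (length(out) == 0L) break
    if (length(out) >= length(keep))
      stop("threshold too aggressive: all individuals flagged as outliers")
    removed_by_iter[[it]] <- keep[out]
    keep <- keep[-out]
    cur <- cur[-out]
  }
  structure(list(genotypes = cur,
                 removed = as.integer(unlist(removed_by_iter)),
                 removed_by_iteration = removed_by_iter,
                 log = do.call(rbind, log_rows),
                 iterations = it,
                 coords = coords,
                 threshold = threshold),
            class = "ca_report")
}

#' @export
print.ca_report <- function(x, ...) {
  cat(sprintf("ca_report: %d iteration(s), %d individual(s) removed, %d retained\n",
              x$iterations, length(x$removed), n_individuals(x$genotypes)))
  print(x$log, row.names = FALSE)
  invisible(x)
}
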