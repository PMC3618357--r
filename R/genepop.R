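#' Read a Genepop file
#'
#' Parses the Genepop text dialect used by LDNE-family software: a title
#' line, one locus name per line (or one comma-separated line), then one or
#' more `Pop` blocks of `id , 045012 003003 ...` rows.  Both 2- and 3-digit
#' allele codes are auto-detected; `00`/`000` denotes a missing allele and a
#' call is treated as missing when either allele is zero.
#'
#' @param path path to a Genepop file.
#' @return A [genotype_matrix()]; population blocks are concatenated with the
#'   block labels kept in `$pop`.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("Genepop parse error: file too short")
  is_pop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3L)
    stop("Genepop parse error: no 'Pop' line found after the locus list")
  locus_lines <- trimws(lines[2:(first_pop - 1L)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) < 1L) stop("Genepop parse error: empty locus list")
  L <- length(loci)

  ids <- character(0)
  pops <- character(0)
  rows1 <- list()
  rows2 <- list()
  width <- NA_integer_
  pop_id <- 0L
  for (ln in seq(first_pop, length(lines))) {
    line <- lines[ln]
    if (grepl("^\\s*pop\\s*$", line, ignore.case = TRUE)) {
      pop_id <- pop_id + 1L
      next
    }
    if (!nzchar(trimws(line))) next
    parts <- strsplit(line, ",")[[1]]
    if (length(parts) < 2L)
      stop("Genepop parse error at line ", ln, ": expected 'id , genotypes'")
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(toks) != L)
      stop("Genepop parse error at line ", ln, ": expected ", L,
           " genotypes, found ", length(toks))
    w <- unique(nchar(toks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("Genepop format error at line ", ln,
           ": inconsistent allele code width")
    w <- w %/% 2L
    if (is.na(width)) width <- w
    if (w != width)
      stop("Genepop format error at line ", ln,
           ": allele code width changes mid-file")
    v1 <- suppressWarnings(as.integer(substr(toks, 1L, width)))
    v2 <- suppressWarnings(as.integer(substr(toks, width + 1L, 2L * width)))
    if (anyNA(v1) || anyNA(v2))
      stop("Genepop parse error at line ", ln, ": non-numeric allele code")
    miss <- v1 == 0L | v2 == 0L
    v1[miss] <- NA_integer_
    v2[miss] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, paste0("pop_", pop_id))
    rows1[[length(rows1) + 1L]] <- v1
    rows2[[length(rows2) + 1L]] <- v2
  }
  if (length(rows1) == 0L) stop("Genepop parse error: no genotype rows")
  gm <- genotype_matrix(do.call(rbind, rows1), do.call(rbind, rows2),
                        individual_ids = ids, locus_names = loci, pop = pops)
  attr(gm, "code_width") <- width
  gm
}

#' Write a Genepop file
#'
#' Deterministic (bit-stable) serialisation readable by [read_genepop()].
#' Missing calls are written as all-zero codes (`"000000"` in 3-digit mode).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @param title title line (first line of the file).
#' @param width allele code width in digits (2 or 3; default 3).
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gm, path, title = "ldnetools export", width = 3L) {
  if (n_individuals(gm) == 0L || n_loci(gm) == 0L)
    stop("refusing to write an empty genotype matrix")
  if (!width %in% c(2L, 3L)) stop("width must be 2 or 3")
  mx <- max(c(gm$a1, gm$a2), na.rm = TRUE)
  if (mx >= 10^width)
    stop("allele code ", mx, " does not fit in ", width, " digits")
  fmt <- paste0("%0", width, "d")
  enc <- function(a1, a2) {
    out <- paste0(sprintf(fmt, ifelse(is.na(a1), 0L, a1)),
                  sprintf(fmt, ifelse(is.na(a2), 0L, a2)))
    out
  }
  pops <- if (is.null(gm$pop)) rep("pop_1", n_individuals(gm)) else as.character(gm$pop)
  lines <- c(title, gm$locus_names)
  for (p in unique(pops)) {
    lines <- c(lines, "Pop")
    for (i in which(pops == p)) {
      lines <- c(lines, paste0(gm$individual_ids[i], " ,  ",
                               paste(enc(gm$a1[i, ], gm$a2[i, ]), collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
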