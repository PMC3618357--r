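#' Genotype-class counts for one allele pair at one locus pair
#'
#' For alleles j (at locus A) and k (at locus B), counts the four
#' unphased-genotype classes that contain at least one copy of each:
#' `x_jjkk` (homozygous at both), `x_jjkh` (homozygous j, heterozygous k),
#' `x_jhkk` (heterozygous j, homozygous k) and `x_jhkh` (the double
#' heterozygote, which contributes half a j-k pairing because the j and k
#' copies may sit on opposite gametes).  Only individuals typed at both
#' loci are counted.
#'
#' @param gm a [genotype_matrix()].
#' @param locus_a,locus_b locus names or indices; must differ
#'   (within-locus disequilibrium is out of scope).
#' @param allele_j,allele_k allele codes at the two loci.
#' @return A list with the four counts and `n_ab`, the number of
#'   individuals jointly typed at both loci.
#' @export
count_genotype_pairs <- function(gm, locus_a, locus_b, allele_j, allele_k) {
  ia <- locus_index(gm, locus_a)
  ib <- locus_index(gm, locus_b)
  if (ia == ib) stop("locus_a and locus_b must differ")
  typed <- !is.na(gm$a1[, ia]) & !is.na(gm$a1[, ib])
  da <- (gm$a1[typed, ia] == allele_j) + (gm$a2[typed, ia] == allele_j)
  db <- (gm$a1[typed, ib] == allele_k) + (gm$a2[typed, ib] == allele_k)
  list(x_jjkk = sum(da == 2L & db == 2L),
       x_jjkh = sum(da == 2L & db == 1L),
       x_jhkk = sum(da == 1L & db == 2L),
       x_jhkh = sum(da == 1L & db == 1L),
       n_ab = sum(typed))
}

#' Composite pair frequency from genotype-class counts
#'
#' The per-individual composite count of j-k pairings,
#' `(2*x_jjkk + x_jjkh + x_jhkk + x_jhkh/2) / n_ab`, in \[0, 2\].  The
#' divisor is the number of jointly typed individuals, the standard
#' composite formulation under which the Burrows disequilibrium
#' `composite - 2*p_j*p_k` vanishes for independent loci (a gamete-count
#' divisor `2*n_ab` is available for comparison but halves the scale and
#' does not vanish under independence).
#'
#' @param counts output of [count_genotype_pairs()].
#' @param divisor `"individuals"` (default, composite scale) or
#'   `"gametes"` (literal gamete-count divisor `2*n_ab`).
#' @return The composite pair frequency.
#' @export
composite_pair_freq <- function(counts, divisor = c("individuals", "gametes")) {
  divisor <- match.arg(divisor)
  if (counts$n_ab < 1L) stop("no individuals jointly typed at both loci")
  num <- 2 * counts$x_jjkk + counts$x_jjkh + counts$x_jhkk + counts$x_jhkh / 2
  num / switch(divisor, individuals = counts$n_ab, gametes = 2 * counts$n_ab)
}

# Vectorised LD statistics for one locus pair, computed on the jointly
# typed subset.  Returns NULL when fewer than 2 individuals are jointly
# typed or either locus is monomorphic there.
pair_ld_stats <- function(gm, ia, ib) {
  typed <- which(!is.na(gm$a1[, ia]) & !is.na(gm$a1[, ib]))
  n <- length(typed)
  if (n < 2L) return(NULL)
  dosage <- function(col) {
    v1 <- gm$a1[typed, col]
    v2 <- gm$a2[typed, col]
    u <- sort(unique(c(v1, v2)))
    Y <- matrix(0L, n, length(u))
    Y[cbind(seq_len(n), match(v1, u))] <- Y[cbind(seq_len(n), match(v1, u))] + 1L
    Y[cbind(seq_len(n), match(v2, u))] <- Y[cbind(seq_len(n), match(v2, u))] + 1L
    list(Y = Y, alleles = u)
  }
  A <- dosage(ia)
  B <- dosage(ib)
  pA <- colSums(A$Y) / (2 * n)
  pB <- colSums(B$Y) / (2 * n)
  # Hardy-Weinberg-deviation-corrected variances: p(1-p) + (f_hom - p^2)
  vA <- pA * (1 - pA) + colSums(A$Y == 2L) / n - pA^2
  vB <- pB * (1 - pB) + colSums(B$Y == 2L) / n - pB^2
  comp <- crossprod(A$Y, B$Y) / (2 * n)           # composite pair frequency
  delta <- comp - 2 * outer(pA, pB)               # Burrows disequilibrium
  denom <- outer(vA, vB)
  defined <- denom > 1e-12
  r2 <- matrix(NA_real_, length(pA), length(pB))
  r2[defined] <- pmin(delta[defined]^2 / denom[defined], 1)
  list(n_ab = n, alleles_a = A$alleles, alleles_b = B$alleles,
       p_a = pA, p_b = pB, delta = delta, r2 = r2, defined = defined)
}

#' Burrows composite LD for a single allele pair
#'
#' The squared correlation of allele j (locus A) with allele k (locus B),
#' built from the Burrows composite disequilibrium and phi-correlation
#' normalisation with Hardy-Weinberg-deviation-corrected variances.  All
#' quantities are computed on the subset of individuals typed at both loci.
#'
#' @inheritParams count_genotype_pairs
#' @return A list: `p_a`, `p_b` (allele frequencies in the jointly typed
#'   subset), `d_a`, `d_b` (homozygote-excess terms), `delta` (composite
#'   disequilibrium), `r2`, `n_ab`, and `defined` (`FALSE` when the
#'   normalising variance vanishes, e.g. a monomorphic locus).
#' @examples
#' gm <- genotype_matrix(matrix(c(1L, 2L, 1L, 2L), 2, 2),
#'                       matrix(c(1L, 2L, 1L, 2L), 2, 2))
#' burrows_r2(gm, 1, 2, 1, 1)$r2   # perfect association
#' @export
burrows_r2 <- function(gm, locus_a, locus_b, allele_j, allele_k) {
  ia <- locus_index(gm, locus_a)
  ib <- locus_index(gm, locus_b)
  if (ia == ib) stop("locus_a and locus_b must differ")
  st <- pair_ld_stats(gm, ia, ib)
  if (is.null(st)) stop("fewer than 2 individuals jointly typed")
  j <- match(allele_j, st$alleles_a)
  k <- match(allele_k, st$alleles_b)
  if (is.na(j) || is.na(k))
    stop("allele not observed among jointly typed individuals")
  typed <- !is.na(gm$a1[, ia]) & !is.na(gm$a1[, ib])
  f_aa <- mean(gm$a1[typed, ia] == allele_j & gm$a2[typed, ia] == allele_j)
  f_bb <- mean(gm$a1[typed, ib] == allele_k & gm$a2[typed, ib] == allele_k)
  list(p_a = st$p_a[j], p_b = st$p_b[k],
       d_a = f_aa - st$p_a[j]^2,
       d_b = f_bb - st$p_b[k]^2,
       delta = st$delta[j, k],
       r2 = st$r2[j, k],
       n_ab = st$n_ab,
       defined = st$defined[j, k])
}

#' Mean filtered r-squared across all locus pairs
#'
#' Computes the Burrows composite r-squared for every allele pair at every
#' locus pair, discards pairs in which either allele's frequency (in the
#' jointly typed subset) falls below `pcrit` (a frequency exactly equal to
#' `pcrit` is retained), and returns the n-weighted mean together with the
#' sampling-bias correction needed for Ne estimation.
#'
#' Each retained allele pair is weighted by `n_ab`, the number of
#' individuals jointly typed at its locus pair, so locus pairs genotyped in
#' more individuals carry more weight under missing data.  The effective
#' sample size `s_eff` is the harmonic mean of `n_ab` over retained locus
#' pairs, and `e_sample_r2 = 1/s_eff + 3.19/s_eff^2` is the expected
#' contribution of finite sample size to the mean r-squared.
#'
#' @param gm a [genotype_matrix()] with at least 2 loci.
#' @param pcrit allele-frequency threshold; alleles with frequency below
#'   `pcrit` are excluded from the average (`pcrit = 0` retains every
#'   observed allele).
#' @return An object of class `ld_summary`: `mean_r2`, `s_eff`,
#'   `e_sample_r2`, `r2_prime` (`mean_r2 - e_sample_r2`), `pcrit`,
#'   `n_pairs_retained`, `n_undefined`, and `pair_table`, a per-locus-pair
#'   data frame (`locus_a`, `locus_b`, `n_ab`, `n_retained`, `sum_w`,
#'   `sum_wr2`) used by the jackknife.
#' @export
mean_r2 <- function(gm, pcrit = 0.01) {
  L <- n_loci(gm)
  if (L < 2L) stop("LD estimation needs at least 2 loci")
  if (pcrit < 0 || pcrit >= 1) stop("pcrit must lie in [0, 1)")
  rows <- list()
  n_undefined <- 0L
  for (ia in 1:(L - 1L)) {
    for (ib in (ia + 1L):L) {
      st <- pair_ld_stats(gm, ia, ib)
      if (is.null(st)) next
      keep <- outer(st$p_a >= pcrit, st$p_b >= pcrit) & st$defined
      n_undefined <- n_undefined +
        sum(outer(st$p_a >= pcrit, st$p_b >= pcrit) & !st$defined)
      n_keep <- sum(keep)
      if (n_keep == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        locus_a = gm$locus_names[ia], locus_b = gm$locus_names[ib],
        n_ab = st$n_ab, n_retained = n_keep,
        sum_w = n_keep * st$n_ab,
        sum_wr2 = st$n_ab * sum(st$r2[keep]))
    }
  }
  if (length(rows) == 0L)
    stop("no allele pairs retained: Pcrit too high for data")
  pair_table <- do.call(rbind, rows)
  mr2 <- sum(pair_table$sum_wr2) / sum(pair_table$sum_w)
  s_eff <- 1 / mean(1 / pair_table$n_ab)
  e_s <- expected_sample_r2(s_eff)
  structure(list(mean_r2 = mr2, s_eff = s_eff, e_sample_r2 = e_s,
                 r2_prime = mr2 - e_s, pcrit = pcrit,
                 n_pairs_retained = sum(pair_table$n_retained),
                 n_undefined = n_undefined, pair_table = pair_table),
            class = "ld_summary")
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf(paste0("ld_summary: mean r2 = %.6g over %d allele pairs ",
                     "(%d locus pairs, Pcrit = %g)\n"),
              x$mean_r2, x$n_pairs_retained, nrow(x$pair_table), x$pcrit))
  cat(sprintf("  s_eff = %.1f, E[r2 | sampling] = %.6g, r2' = %.6g\n",
              x$s_eff, x$e_sample_r2, x$r2_prime))
  invisible(x)
}

#' Per-allele-pair LD table
#'
#' Long-format audit dump: one row per allele pair per locus pair with the
#' jointly-typed sample size, allele frequencies, Burrows disequilibrium
#' and r-squared.  Suitable for CSV export.
#'
#' @inheritParams mean_r2
#' @return A data frame with columns `locus_a`, `locus_b`, `allele_j`,
#'   `allele_k`, `n_ab`, `p_a`, `p_b`, `delta`, `r2`, `retained`.
#' @export
ld_pair_table <- function(gm, pcrit = 0.01) {
  L <- n_loci(gm)
  if (L < 2L) stop("LD estimation needs at least 2 loci")
  out <- list()
  for (ia in 1:(L - 1L)) {
    for (ib in (ia + 1L):L) {
      st <- pair_ld_stats(gm, ia, ib)
      if (is.null(st)) next
      grid <- expand.grid(j = seq_along(st$alleles_a),
                          k = seq_along(st$alleles_b))
      out[[length(out) + 1L]] <- data.frame(
        locus_a = gm$locus_names[ia], locus_b = gm$locus_names[ib],
        allele_j = st$alleles_a[grid$j], allele_k = st$alleles_b[grid$k],
        n_ab = st$n_ab,
        p_a = st$p_a[grid$j], p_b = st$p_b[grid$k],
        delta = st$delta[cbind(grid$j, grid$k)],
        r2 = st$r2[cbind(grid$j, grid$k)],
        retained = st$p_a[grid$j] >= pcrit & st$p_b[grid$k] >= pcrit &
          st$defined[cbind(grid$j, grid$k)])
    }
  }
  do.call(rbind, out)
}
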