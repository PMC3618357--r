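# Random diploid genotype matrix with optional missingness, for property tests
random_gm <- function(n, L, alleles_per_locus = 4L, miss_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a1 <- matrix(sample.int(alleles_per_locus, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample.int(alleles_per_locus, n * L, replace = TRUE), n, L)
  if (miss_prob > 0) {
    mask <- matrix(runif(n * L) < miss_prob, n, L)
    # keep at least 2 typed loci per individual
    for (i in seq_len(n)) {
      while (sum(!mask[i, ]) < 2L) mask[i, sample.int(L, 1L)] <- FALSE
    }
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  genotype_matrix(a1, a2)
}

# Scalar brute-force Burrows r2 oracle: per-individual genotype-class
# classification per the four-class table, independent of the vectorised
# dosage/crossprod path.
oracle_r2 <- function(gm, ia, ib, j, k) {
  typed <- which(!is.na(gm$a1[, ia]) & !is.na(gm$a1[, ib]))
  n <- length(typed)
  comp <- 0
  p_j <- 0; p_k <- 0; f_jj <- 0; f_kk <- 0
  for (i in typed) {
    ga <- c(gm$a1[i, ia], gm$a2[i, ia])
    gb <- c(gm$a1[i, ib], gm$a2[i, ib])
    nj <- sum(ga == j)
    nk <- sum(gb == k)
    # genotype classes: jj*kk -> 2, jj*khet or jhet*kk -> 1, double het -> 1/2
    if (nj == 2 && nk == 2) comp <- comp + 2
    else if (nj == 2 && nk == 1) comp <- comp + 1
    else if (nj == 1 && nk == 2) comp <- comp + 1
    else if (nj == 1 && nk == 1) comp <- comp + 0.5
    p_j <- p_j + nj / 2
    p_k <- p_k + nk / 2
    f_jj <- f_jj + (nj == 2)
    f_kk <- f_kk + (nk == 2)
  }
  p_j <- p_j / n; p_k <- p_k / n
  d_j <- f_jj / n - p_j^2
  d_k <- f_kk / n - p_k^2
  delta <- comp / n - 2 * p_j * p_k
  den <- (p_j * (1 - p_j) + d_j) * (p_k * (1 - p_k) + d_k)
  if (den <= 1e-12) return(NA_real_)
  min(delta^2 / den, 1)
}

# Brute-force filtered weighted mean r2 built on the oracle
oracle_mean_r2 <- function(gm, pcrit) {
  L <- n_loci(gm)
  sw <- 0; swr <- 0; ns <- c()
  for (ia in 1:(L - 1)) for (ib in (ia + 1):L) {
    typed <- which(!is.na(gm$a1[, ia]) & !is.na(gm$a1[, ib]))
    n <- length(typed)
    if (n < 2) next
    ua <- sort(unique(c(gm$a1[typed, ia], gm$a2[typed, ia])))
    ub <- sort(unique(c(gm$a1[typed, ib], gm$a2[typed, ib])))
    pa <- sapply(ua, function(u) sum(c(gm$a1[typed, ia], gm$a2[typed, ia]) == u)) / (2 * n)
    pb <- sapply(ub, function(u) sum(c(gm$a1[typed, ib], gm$a2[typed, ib]) == u)) / (2 * n)
    used <- FALSE
    for (j in seq_along(ua)) for (k in seq_along(ub)) {
      if (pa[j] < pcrit || pb[k] < pcrit) next
      r2 <- oracle_r2(gm, ia, ib, ua[j], ub[k])
      if (is.na(r2)) next
      sw <- sw + n; swr <- swr + n * r2; used <- TRUE
    }
    if (used) ns <- c(ns, n)
  }
  list(mean_r2 = swr / sw, s_eff = 1 / mean(1 / ns))
}

# Small founder spectrum shared by simulation tests (modest allele counts
# keep brute-force oracles fast)
toy_spectrum <- function(seed = 101) {
  spec <- spectrum_spec(paste0("L", 1:4), na = c(6L, 5L, 6L, 4L),
                        max_freq = c(0.4, 0.35, 0.3, 0.45),
                        low_frac = c(0, 0, 0, 0))
  synthesize_spectrum(spec, seed = seed)
}

# Cache for the expensive acceptance-scale simulation arms, computed once
# per test run and shared across acceptance criteria blocks
.arm_cache <- new.env(parent = emptyenv())
arm_cached <- function(key, expr) {
  if (is.null(.arm_cache[[key]])) .arm_cache[[key]] <- force(expr)
  .arm_cache[[key]]
}
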