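#' Expected sampling contribution to mean r-squared
#'
#' The upward bias in the mean squared allele correlation induced by
#' sampling `s` diploid individuals: `1/s + 3.19/s^2`.  Subtracting this
#' from the observed mean r-squared isolates the drift signal used to
#' estimate Ne.
#'
#' @param s number of individuals sampled (>= 2); may be fractional when an
#'   effective (harmonic-mean) sample size is used under missing data.
#' @return `1/s + 3.19/s^2`.
#' @export
expected_sample_r2 <- function(s) {
  if (any(s < 2)) stop("sample size must be >= 2")
  1 / s + 3.19 / s^2
}

#' Effective population size from the drift component of r-squared
#'
#' Inverts the drift expectation `r2' = 1/(3*Ne) - 0.69/Ne^2` for Ne,
#' giving the quadratic solution
#' `Ne = (1/3 + sqrt(1/9 - 2.76 * r2')) / (2 * r2')`.
#' A negative `r2'` (observed LD below the sampling expectation) yields a
#' negative estimate, which signals a large, undefined Ne rather than an
#' error.  When the radicand is negative (`r2' > 1/24.84`, i.e. extremely
#' strong LD where the second-order drift correction breaks down) the
#' first-order estimate `1/(3*r2')` is returned and flagged via the
#' `"fallback"` attribute.
#'
#' @param r2_prime bias-corrected mean r-squared (vectorised).
#' @return Ne estimate(s); `Inf` where `r2_prime` is exactly 0 (no drift
#'   signal).
#' @examples
#' ne_from_r2prime(1 / 3000 - 0.69 / 1e6)  # = 1000
#' @export
ne_from_r2prime <- function(r2_prime) {
  out <- numeric(length(r2_prime))
  fallback <- logical(length(r2_prime))
  for (i in seq_along(r2_prime)) {
    rp <- r2_prime[i]
    if (is.na(rp)) { out[i] <- NA_real_; next }
    if (rp == 0) { out[i] <- Inf; next }
    rad <- 1 / 9 - 2.76 * rp
    if (rad < 0) {
      out[i] <- 1 / (3 * rp)
      fallback[i] <- TRUE
    } else {
      out[i] <- (1 / 3 + sqrt(rad)) / (2 * rp)
    }
  }
  if (any(fallback)) {
    warning("second-order correction out of range; first-order estimate used")
    attr(out, "fallback") <- fallback
  }
  out
}

#' Jackknife confidence interval for an LD summary
#'
#' Delete-one-locus-pair jackknife on the weighted mean r-squared: each
#' locus pair is removed in turn, the weighted mean recomputed, and the
#' jackknife standard error converted into a normal-approximation interval
#' on `r2'` which is then mapped through [ne_from_r2prime()].  Because Ne
#' is monotone decreasing in `r2'`, the lower Ne bound comes from the upper
#' `r2'` bound; a non-positive lower `r2'` bound maps to an infinite upper
#' Ne bound.
#'
#' @param ld an `ld_summary` from [mean_r2()] with at least 3 locus pairs.
#' @param conf confidence level (default 0.95).
#' @return A list: `ci_lower`, `ci_upper` (Ne scale; possibly infinite),
#'   `se_r2` (jackknife standard error of the mean r-squared), and the
#'   `r2'` bounds `r2p_lower`, `r2p_upper`.
#' @export
jackknife_ci <- function(ld, conf = 0.95) {
  stopifnot(inherits(ld, "ld_summary"))
  pt <- ld$pair_table
  m <- nrow(pt)
  if (m < 3L)
    return(list(ci_lower = NA_real_, ci_upper = NA_real_, se_r2 = NA_real_,
                r2p_lower = NA_real_, r2p_upper = NA_real_, defined = FALSE))
  tot_wr2 <- sum(pt$sum_wr2)
  tot_w <- sum(pt$sum_w)
  theta <- (tot_wr2 - pt$sum_wr2) / (tot_w - pt$sum_w)
  se <- sqrt((m - 1) / m * sum((theta - mean(theta))^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  r2p_lower <- ld$r2_prime - z * se
  r2p_upper <- ld$r2_prime + z * se
  map <- function(rp) {
    if (rp <= 0) return(Inf)
    suppressWarnings(ne_from_r2prime(rp)[1])
  }
  list(ci_lower = map(r2p_upper), ci_upper = map(r2p_lower), se_r2 = se,
       r2p_lower = r2p_lower, r2p_upper = r2p_upper, defined = TRUE)
}

#' Estimate effective population size from linkage disequilibrium
#'
#' The full LD-Ne pipeline: mean Burrows r-squared over all locus pairs
#' with `pcrit` filtering ([mean_r2()]), subtraction of the finite-sample
#' expectation, inversion of the drift relation ([ne_from_r2prime()]), and
#' a delete-one-locus-pair jackknife confidence interval.
#'
#' @inheritParams mean_r2
#' @param ci compute the jackknife confidence interval (default `TRUE`).
#' @param conf confidence level.
#' @return An object of class `ne_estimate`: `ne_hat` (negative values
#'   signal a large, undefined Ne), `ci_lower`, `ci_upper`, `r2_prime`,
#'   `mean_r2`, `s_eff`, `pcrit`, `n_locus_pairs`, `n_pairs_retained`.
#' @export
estimate_ne <- function(gm, pcrit = 0.01, ci = TRUE, conf = 0.95) {
  ld <- mean_r2(gm, pcrit)
  ne <- suppressWarnings(ne_from_r2prime(ld$r2_prime)[1])
  jk <- if (ci) jackknife_ci(ld, conf) else
    list(ci_lower = NA_real_, ci_upper = NA_real_, se_r2 = NA_real_)
  structure(list(ne_hat = ne, ci_lower = jk$ci_lower, ci_upper = jk$ci_upper,
                 se_r2 = jk$se_r2, r2_prime = ld$r2_prime,
                 mean_r2 = ld$mean_r2, s_eff = ld$s_eff, pcrit = pcrit,
                 n_locus_pairs = nrow(ld$pair_table),
                 n_pairs_retained = ld$n_pairs_retained,
                 ld = ld),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  fmt <- function(v) {
    if (is.na(v)) "NA" else if (!is.finite(v)) "Infinite"
    else format(round(v, 1), big.mark = ",")
  }
  cat(sprintf("LD-Ne estimate (Pcrit = %g): %s\n", x$pcrit, fmt(x$ne_hat)))
  if (!is.na(x$ne_hat) && is.finite(x$ne_hat) && x$ne_hat < 0)
    cat("  (negative estimate: Ne is large/undefined at this sample size)\n")
  cat(sprintf("  95%% CI: [%s, %s]   r2' = %.3g   S_eff = %.1f   pairs = %d\n",
              fmt(x$ci_lower), fmt(x$ci_upper), x$r2_prime, x$s_eff,
              x$n_pairs_retained))
  invisible(x)
}

#' Harmonic mean of Ne estimates
#'
#' Aggregates replicate or iterated Ne estimates by their harmonic mean, the
#' drift-appropriate average (dominated by small estimates).  Non-positive
#' and non-finite estimates (which signal a large, undefined Ne) are
#' excluded; the number excluded is reported as an attribute.
#'
#' @param ne numeric vector of Ne estimates (or a list of `ne_estimate`
#'   objects).
#' @return Harmonic mean of the positive estimates, with attribute
#'   `"n_excluded"`.
#' @examples
#' harmonic_mean_ne(c(500, 2000))      # 800
#' harmonic_mean_ne(c(1000, -5000))    # 1000, one exclusion
#' @export
harmonic_mean_ne <- function(ne) {
  if (is.list(ne)) ne <- vapply(ne, function(x) x$ne_hat, numeric(1))
  if (length(ne) < 1L) stop("no estimates supplied")
  pos <- ne[is.finite(ne) & ne > 0]
  if (length(pos) == 0L) stop("no positive, finite Ne estimates to average")
  structure(length(pos) / sum(1 / pos), n_excluded = length(ne) - length(pos))
}
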