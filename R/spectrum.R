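#' Allele-frequency spectrum specification
#'
#' Describes, locus by locus, the marginal structure a synthetic
#' microsatellite allele-frequency spectrum must reproduce: the number of
#' alleles, the maximum allele frequency, and the fraction of alleles at
#' frequency at most 0.01.  Optional band counts (alleles above 0.10 and
#' below 0.001) refine the shape of the simulated tail when known.
#'
#' @param locus character vector of locus names.
#' @param na integer vector: number of alleles per locus (>= 2).
#' @param max_freq numeric vector: target maximum allele frequency per locus,
#'   each in \[1/na, 1).
#' @param low_frac numeric vector: target fraction of alleles with frequency
#'   <= 0.01, each in \[0, 1).
#' @param n_gt10 optional integer vector: alleles with frequency > 0.10
#'   (including the maximum).
#' @param n_lt001 optional integer vector: alleles with frequency < 0.001.
#' @return An object of class `spectrum_spec` (a data frame).
#' @seealso [default_spectrum_spec()] for the seven-locus panel the package
#'   ships as its study default.
#' @export
spectrum_spec <- function(locus, na, max_freq, low_frac,
                          n_gt10 = NULL, n_lt001 = NULL) {
  na <- as.integer(na)
  if (any(na < 2L)) stop("each locus needs na >= 2")
  if (any(max_freq < 1 / na - 1e-12) || any(max_freq >= 1))
    stop("max_freq must lie in [1/na, 1): a maximum below 1/na is infeasible")
  if (any(low_frac < 0) || any(low_frac >= 1))
    stop("low_frac must lie in [0, 1)")
  if (is.null(n_gt10)) n_gt10 <- pmax(1L, as.integer(max_freq > 0.10))
  n_low <- as.integer(round(na * low_frac))
  if (is.null(n_lt001)) n_lt001 <- as.integer(n_low %/% 2L)
  if (any(n_gt10 + n_low > na))
    stop("band counts exceed the number of alleles")
  structure(data.frame(locus = as.character(locus), na = na,
                       max_freq = max_freq, low_frac = low_frac,
                       n_gt10 = as.integer(n_gt10),
                       n_lt001 = pmin(as.integer(n_lt001), n_low)),
            class = c("spectrum_spec", "data.frame"))
}

#' Default seven-locus microsatellite spectrum specification
#'
#' The package's reference panel: seven highly polymorphic microsatellite
#' loci with 24-38 alleles each, per-locus maximum frequencies from 0.127
#' to 0.735, and roughly 65% of all alleles at frequency <= 0.01 -- the
#' allele-frequency structure of a large Spanish mackerel (*Scomberomorus
#' commerson*) genotype collection.  Per-locus sample sizes (`s_l`, of 5413
#' individuals) are attached for the companion missingness model.
#'
#' @return A `spectrum_spec` with an `s_l` attribute (individuals scored per
#'   locus) and `s_total` (total individuals sampled).
#' @export
default_spectrum_spec <- function() {
  locus <- c("SCA30", "SM3", "SM37", "SCA47", "SCA49", "90RTE", "SCA8")
  s_l <- c(5210L, 5206L, 4611L, 4781L, 4829L, 5266L, 5139L)
  na <- c(36L, 32L, 37L, 27L, 25L, 24L, 38L)
  max_freq <- c(0.178, 0.183, 0.127, 0.486, 0.248, 0.735, 0.216)
  n_gt10 <- c(2L, 4L, 2L, 3L, 5L, 1L, 4L)
  n_mid <- c(17L, 8L, 16L, 4L, 5L, 6L, 12L)   # alleles in (0.001, 0.01]
  n_lt001 <- c(8L, 13L, 9L, 14L, 8L, 11L, 11L)
  spec <- spectrum_spec(locus, na, max_freq,
                        low_frac = (n_mid + n_lt001) / na,
                        n_gt10 = n_gt10, n_lt001 = n_lt001)
  attr(spec, "s_l") <- s_l
  attr(spec, "s_total") <- 5413L
  spec
}

geomspace <- function(a, b, n) {
  if (n <= 0L) return(numeric(0))
  if (n == 1L) return(a)
  exp(seq(log(a), log(b), length.out = n))
}

# Deterministic banded base shape for one locus, head (= fmax) excluded.
# Band masses are balanced so the tail sums to exactly 1 - fmax while the
# rare bands keep their nominal positions; the common/intermediate bands
# absorb the remaining mass.
spectrum_base_tail <- function(na, fmax, n_gt10, n_low, n_vlow) {
  n_extra <- max(0L, n_gt10 - 1L)              # > 0.10, besides the head
  n_low01 <- n_low - n_vlow                    # (0.001, 0.01]
  n_mid <- na - n_gt10 - n_low                 # (0.01, 0.10]
  if (n_mid < 0L) stop("band counts exceed the number of alleles")
  vlow <- geomspace(9e-4, 1.2e-4, n_vlow)
  low01 <- geomspace(9.5e-3, 1.1e-3, n_low01)
  R <- 1 - fmax - sum(vlow) - sum(low01)       # mass left for extras + mid
  if (R <= 0)
    stop("infeasible spectrum: rare-allele bands exceed available mass")
  extras <- geomspace(min(0.93 * fmax, 0.45), 0.105, n_extra)
  m_mid_min <- n_mid * 0.0111
  if (sum(extras) > R - m_mid_min && n_extra > 0L)
    extras <- extras * (R - m_mid_min) / sum(extras)
  m_mid <- R - sum(extras)
  if (n_mid > 0L) {
    if (m_mid <= 0) stop("infeasible spectrum: no mass left for mid band")
    # geometric shape flattened until the largest mid value fits its band
    shape <- geomspace(1, 0.011 / 0.095, n_mid)
    mid <- m_mid * shape / sum(shape)
    for (i in 1:40) {
      if (max(mid) <= 0.0955 || max(mid) <= m_mid / n_mid + 1e-9) break
      shape <- sqrt(shape)                     # move toward uniform
      mid <- m_mid * shape / sum(shape)
    }
  } else {
    if (m_mid > 1e-9 && n_extra > 0L) extras <- extras * (R / sum(extras))
    mid <- numeric(0)
  }
  c(extras, mid, low01, vlow)
}

#' Synthesize an allele-frequency spectrum
#'
#' Generates, per locus, a frequency vector with exactly `na` alleles whose
#' maximum equals the target maximum and whose fraction of alleles at
#' frequency <= 0.01 is within 10 percentage points of target.  The head
#' allele is pinned at the target maximum; the tail is a banded
#' geometric-decay series perturbed by a Dirichlet jitter and renormalised,
#' with rejection sampling until the marginal constraints hold.
#'
#' @param spec a [spectrum_spec()].
#' @param seed integer seed; the result is reproducible given the seed.
#' @param jitter Dirichlet concentration; larger values track the base
#'   shape more closely.
#' @param max_tries rejection-sampling cap per locus.
#' @return An [afreq_table()] with allele codes `1..na` per locus.
#' @examples
#' tab <- synthesize_spectrum(default_spectrum_spec(), seed = 1)
#' sapply(tab$freqs, max)
#' @export
synthesize_spectrum <- function(spec, seed = NULL, jitter = 400, max_tries = 200L) {
  stopifnot(inherits(spec, "spectrum_spec"))
  with_seed(seed, {
    freqs <- vector("list", nrow(spec))
    for (l in seq_len(nrow(spec))) {
      na <- spec$na[l]
      fmax <- spec$max_freq[l]
      if (abs(fmax - 1 / na) < 1e-9) {         # forced uniform spectrum
        f <- rep(1 / na, na)
        names(f) <- seq_len(na)
        freqs[[l]] <- f
        next
      }
      n_low <- as.integer(round(na * spec$low_frac[l]))
      base <- spectrum_base_tail(na, fmax, spec$n_gt10[l], n_low, spec$n_lt001[l])
      stopifnot(length(base) == na - 1L)
      share <- base / sum(base)
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        g <- stats::rgamma(na - 1L, shape = jitter * share, rate = 1)
        g <- pmax(g, 1e-300)
        tail <- (1 - fmax) * g / sum(g)
        if (max(tail) >= fmax) next
        frac_low <- sum(tail <= 0.01) / na
        if (abs(frac_low - spec$low_frac[l]) > 0.10) next
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not satisfy spectrum constraints for locus '",
             spec$locus[l], "' after ", max_tries, " tries")
      f <- c(fmax, sort(tail, decreasing = TRUE))
      f <- f / sum(f)
      names(f) <- seq_len(na)
      freqs[[l]] <- f
    }
    names(freqs) <- spec$locus
    afreq_table(spec$locus, freqs)
  })
}
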