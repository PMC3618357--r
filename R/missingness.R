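#' Missing-data patterns for simulated genotypes
#'
#' Simulated genotypes are fully typed; field data are not.  A
#' `missingness_pattern` describes how to knock loci out of a simulated
#' sample so that its missing-data structure matches a genotyping campaign.
#' Three modes are supported:
#'
#' * `"probability"`: independent per-locus Bernoulli missingness with the
#'   given rates;
#' * `"donor"`: each simulated individual's missing-locus mask is drawn with
#'   replacement from a donor table of observed masks (preserves
#'   across-locus correlation exactly);
#' * `"typed_count"`: first draw how many loci an individual is missing
#'   (from `count_probs`, a distribution over 0, 1, 2, ... missing loci),
#'   then pick which loci proportionally to per-locus missing weights.
#'
#' @param mode one of `"probability"`, `"donor"`, `"typed_count"`.
#' @param probs numeric vector of per-locus missing probabilities in \[0, 1)
#'   (`"probability"` mode) or per-locus weights (`"typed_count"` mode).
#' @param donor_masks logical matrix (individuals x loci), `TRUE` = missing
#'   (`"donor"` mode); every row must leave at least 2 typed loci.
#' @param count_probs numeric vector of probabilities for 0, 1, 2, ...
#'   missing loci (`"typed_count"` mode); must sum to 1.
#' @return An object of class `missingness_pattern`.
#' @export
missingness_pattern <- function(mode = c("probability", "donor", "typed_count"),
                                probs = NULL, donor_masks = NULL,
                                count_probs = NULL) {
  mode <- match.arg(mode)
  if (mode == "probability") {
    stopifnot(!is.null(probs), all(probs >= 0), all(probs < 1))
  } else if (mode == "donor") {
    stopifnot(!is.null(donor_masks), is.matrix(donor_masks))
    donor_masks <- donor_masks > 0
    if (any(rowSums(!donor_masks) < 2L))
      stop("every donor mask must leave at least 2 typed loci")
  } else {
    stopifnot(!is.null(probs), all(probs >= 0), !is.null(count_probs))
    if (abs(sum(count_probs) - 1) > 1e-9) stop("count_probs must sum to 1")
    if (length(count_probs) < 1L) stop("count_probs is empty")
  }
  structure(list(mode = mode, probs = probs, donor_masks = donor_masks,
                 count_probs = count_probs),
            class = "missingness_pattern")
}

#' Default calibrated missingness pattern
#'
#' The package's reference missing-data model, calibrated to the seven-locus
#' mackerel panel of [default_spectrum_spec()]: 71% of individuals typed at
#' all 7 loci, 12% at 6, 10% at 5 and 7% at 4, with the loci knocked out in
#' proportion to the per-locus missingness rates implied by the per-locus
#' sample sizes (1 - S_L/5413).  Uses `"typed_count"` mode because the
#' empirical missingness is correlated across loci: independent per-locus
#' knockouts with the same marginal rates would put far too few individuals
#' in the fully-typed class.
#'
#' @return A `missingness_pattern` for a 7-locus panel.
#' @export
default_missingness <- function() {
  spec <- default_spectrum_spec()
  rates <- 1 - attr(spec, "s_l") / attr(spec, "s_total")
  missingness_pattern("typed_count", probs = rates,
                      count_probs = c(0.71, 0.12, 0.10, 0.07))
}

#' Apply a missingness pattern to a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param pattern a [missingness_pattern()]; its locus dimension must match
#'   `gm`.
#' @param seed integer seed for reproducibility.
#' @param max_retries redraws allowed per individual before failing when a
#'   drawn mask would leave fewer than 2 typed loci.
#' @return A `genotype_matrix` with calls knocked out; the realised
#'   distribution of typed-locus counts is attached as attribute
#'   `"typed_count_table"`.
#' @export
apply_missingness <- function(gm, pattern, seed = NULL, max_retries = 100L) {
  stopifnot(inherits(pattern, "missingness_pattern"))
  n <- n_individuals(gm)
  L <- n_loci(gm)
  if (pattern$mode %in% c("probability", "typed_count") &&
      length(pattern$probs) != L)
    stop("pattern has ", length(pattern$probs), " loci; genotypes have ", L)
  if (pattern$mode == "donor" && ncol(pattern$donor_masks) != L)
    stop("donor mask locus dimension mismatch")
  with_seed(seed, {
    mask <- matrix(FALSE, n, L)
    if (pattern$mode == "probability") {
      for (i in seq_len(n)) {
        for (try in seq_len(max_retries)) {
          m <- stats::runif(L) < pattern$probs
          if (sum(!m) >= 2L) break
          if (try == max_retries)
            stop("could not draw a mask leaving >= 2 typed loci")
        }
        mask[i, ] <- m
      }
    } else if (pattern$mode == "donor") {
      rows <- sample.int(nrow(pattern$donor_masks), n, replace = TRUE)
      mask <- pattern$donor_masks[rows, , drop = FALSE]
    } else {
      k <- sample.int(length(pattern$count_probs), n, replace = TRUE,
                      prob = pattern$count_probs) - 1L
      if (any(k > L - 2L)) stop("count_probs allows fewer than 2 typed loci")
      w <- pattern$probs
      if (all(w == 0)) w <- rep(1, L)
      for (i in seq_len(n)) {
        if (k[i] > 0L)
          mask[i, sample.int(L, k[i], prob = w)] <- TRUE
      }
    }
    a1 <- gm$a1
    a2 <- gm$a2
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
    out <- genotype_matrix(a1, a2, gm$individual_ids, gm$locus_names, gm$pop)
    attr(out, "typed_count_table") <- table(factor(rowSums(!mask), levels = 0:L))
    out
  })
}
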