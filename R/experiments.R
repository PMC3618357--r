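#' Divergence / immigrant-contamination experiment driver
#'
#' Founds one population from a synthetic allele-frequency spectrum, evolves
#' `n_pops` independent copies over each divergence horizon at size `n`
#' (hybrid drift path: frequency-level drift plus terminal individual-based
#' generations), samples `s` genotypes per population, and then, per
#' horizon:
#'
#' * averages pairwise Weir-Cockerham theta over all population pairs;
#' * estimates LD-Ne per population (no-immigrant arm) at each `pcrit`,
#'   before and (optionally) after iterative CA cleaning;
#' * builds directed mixtures in which `m` focal genotypes are replaced by
#'   donors from another population, re-estimates Ne before/after cleaning,
#'   and scores how many planted immigrants the cleaning removed.
#'
#' Sampled genotypes receive the missingness pattern before estimation, as
#' in a real genotyping campaign.
#'
#' @param spectrum an [afreq_table()] founder spectrum (e.g. from
#'   [synthesize_spectrum()]).
#' @param n population size (default 10000).
#' @param s sample size per population (default 5413).
#' @param generations vector of divergence horizons.
#' @param n_pops number of replicate populations (default 10).
#' @param m immigrants per mixture (default 100).
#' @param pcrits allele-frequency thresholds at which to estimate Ne.
#' @param n_mixtures directed (focal, donor) mixtures per horizon; 0 skips
#'   the immigrant arm; `NULL` uses all `n_pops * (n_pops - 1)`.
#' @param missingness a [missingness_pattern()] or `NULL` for fully typed
#'   samples.
#' @param ib_generations terminal individual-based generations.
#' @param estimate_ne_flag compute Ne estimates (set `FALSE` for an
#'   FST-only run).
#' @param clean run iterative CA cleaning (default `TRUE` when Ne is
#'   estimated).
#' @param threshold,max_iter CA cleaning parameters.
#' @param compute_fst average pairwise theta per horizon.
#' @param seed integer seed; all randomness derives from it.
#' @return A list with data frames `fst` (`generations`, `mean_fst`),
#'   `no_immigrants` (per population and pcrit: `ne`, `ne_cleaned`,
#'   `n_removed`), and `mixtures` (per mixture and pcrit: `ne_before`,
#'   `ne_after`, `detected`, `n_removed`, `iterations`).
#' @export
run_divergence_experiment <- function(spectrum, n = 10000L, s = 5413L,
                                      generations = c(100L, 200L, 500L, 1000L, 2000L),
                                      n_pops = 10L, m = 100L,
                                      pcrits = c(0, 0.01),
                                      n_mixtures = NULL,
                                      missingness = default_missingness(),
                                      ib_generations = 8L,
                                      estimate_ne_flag = TRUE,
                                      clean = TRUE,
                                      threshold = 2, max_iter = 10L,
                                      compute_fst = TRUE,
                                      seed = NULL) {
  if (s > n) stop("sample size s cannot exceed population size n")
  if (is.null(n_mixtures)) n_mixtures <- n_pops * (n_pops - 1L)
  with_seed(seed, {
    fst_rows <- list()
    noimm_rows <- list()
    mix_rows <- list()
    for (g in generations) {
      samples <- vector("list", n_pops)
      for (p in seq_len(n_pops)) {
        pop <- evolve_population(spectrum, n, g, ib_generations)
        smp <- sample_individuals(pop, s)
        samples[[p]] <- smp
      }
      if (compute_fst) {
        th <- c()
        for (i in 1:(n_pops - 1L)) for (j in (i + 1L):n_pops)
          th <- c(th, pairwise_fst(samples[[i]], samples[[j]]))
        fst_rows[[length(fst_rows) + 1L]] <-
          data.frame(generations = g, mean_fst = mean(th))
      }
      if (!estimate_ne_flag) next
      obs <- lapply(samples, function(x) {
        if (is.null(missingness)) x else apply_missingness(x, missingness)
      })
      for (p in seq_len(n_pops)) {
        cleaned <- if (clean)
          iterative_clean(obs[[p]], threshold, max_iter) else NULL
        for (pc in pcrits) {
          ne0 <- estimate_ne(obs[[p]], pc, ci = FALSE)$ne_hat
          ne1 <- if (clean)
            estimate_ne(cleaned$genotypes, pc, ci = FALSE)$ne_hat else NA_real_
          noimm_rows[[length(noimm_rows) + 1L]] <- data.frame(
            generations = g, pop = p, pcrit = pc, ne = ne0, ne_cleaned = ne1,
            n_removed = if (clean) length(cleaned$removed) else NA_integer_)
        }
      }
      if (n_mixtures > 0L) {
        pairs <- expand.grid(focal = seq_len(n_pops), donor = seq_len(n_pops))
        pairs <- pairs[pairs$focal != pairs$donor, ]
        if (n_mixtures < nrow(pairs))
          pairs <- pairs[sample.int(nrow(pairs), n_mixtures), ]
        for (q in seq_len(nrow(pairs))) {
          mixed <- mix_immigrants(obs[[pairs$focal[q]]],
                                  obs[[pairs$donor[q]]], m)
          truth <- attr(mixed, "immigrant_idx")
          cleaned <- if (clean)
            iterative_clean(mixed, threshold, max_iter) else NULL
          detected <- if (clean) sum(cleaned$removed %in% truth) else NA_integer_
          for (pc in pcrits) {
            ne0 <- estimate_ne(mixed, pc, ci = FALSE)$ne_hat
            ne1 <- if (clean)
              estimate_ne(cleaned$genotypes, pc, ci = FALSE)$ne_hat else NA_real_
            mix_rows[[length(mix_rows) + 1L]] <- data.frame(
              generations = g, focal = pairs$focal[q], donor = pairs$donor[q],
              pcrit = pc, ne_before = ne0, ne_after = ne1,
              detected = detected,
              n_removed = if (clean) length(cleaned$removed) else NA_integer_,
              iterations = if (clean) cleaned$iterations else NA_integer_)
          }
        }
      }
    }
    list(fst = if (length(fst_rows)) do.call(rbind, fst_rows),
         no_immigrants = if (length(noimm_rows)) do.call(rbind, noimm_rows),
         mixtures = if (length(mix_rows)) do.call(rbind, mix_rows))
  })
}

#' Non-target-species contamination experiment
#'
#' Adds increasing numbers of genotypes from a surrogate non-target species
#' to a clean focal sample and tracks the LD-Ne estimate.  The surrogate is
#' an independent population founded from an independently synthesized
#' spectrum (no shared ancestry) in which the loci named in
#' `nonamplifying` are wholly missing, emulating a congener that amplifies
#' at only a subset of the focal panel.  A final CA cleaning pass scores
#' how many contaminants the first iteration removes.
#'
#' @param focal a cleaned focal [genotype_matrix()].
#' @param contaminant_counts numbers of contaminants to add progressively.
#' @param pcrits thresholds at which to estimate Ne.
#' @param spectrum_spec spectrum specification for the surrogate species
#'   (defaults to the package panel; it is re-synthesized with its own
#'   seed, so the surrogate shares no allele-frequency structure).
#' @param nonamplifying locus names set wholly missing in the surrogate.
#' @param threshold,max_iter CA cleaning parameters.
#' @param seed integer seed.
#' @return A list: `grid` (data frame `n_added` x `pcrit` with `ne`),
#'   `cleaning` (for the largest count: contaminants removed in the first
#'   iteration and in total).
#' @export
run_contamination_experiment <- function(focal,
                                         contaminant_counts = c(0L, 1L, 2L, 4L, 8L, 16L, 32L, 64L, 100L, 200L),
                                         pcrits = c(0, 0.01),
                                         spectrum_spec = default_spectrum_spec(),
                                         nonamplifying = c("SCA47", "SCA49"),
                                         threshold = 2, max_iter = 10L,
                                         seed = NULL) {
  with_seed(seed, {
    kmax <- max(contaminant_counts)
    surrogate_freqs <- synthesize_spectrum(spectrum_spec)
    # a non-target species has unrelated allele identities: permute which
    # allele code carries which frequency, so common surrogate alleles are
    # typically rare or absent in the focal population
    surrogate_freqs$freqs <- lapply(surrogate_freqs$freqs, function(f) {
      names(f) <- sample(names(f))
      f
    })
    pool <- found_population(surrogate_freqs, max(4L, 2L * kmax))
    drop <- match(nonamplifying, pool$locus_names)
    if (anyNA(drop)) stop("nonamplifying loci not in the panel")
    a1 <- pool$a1
    a2 <- pool$a2
    a1[, drop] <- NA_integer_
    a2[, drop] <- NA_integer_
    pool <- genotype_matrix(a1, a2, pool$individual_ids,
                            spectrum_spec$locus)
    if (!identical(pool$locus_names, focal$locus_names))
      stop("focal sample must use the surrogate's locus panel")
    picks <- sample.int(n_individuals(pool), kmax)
    rows <- list()
    cleaning <- NULL
    for (k in contaminant_counts) {
      gm <- if (k == 0L) focal else {
        add <- pool[picks[seq_len(k)]]
        genotype_matrix(rbind(focal$a1, add$a1), rbind(focal$a2, add$a2),
                        c(focal$individual_ids,
                          paste0("contam_", seq_len(k))),
                        focal$locus_names)
      }
      for (pc in pcrits) {
        rows[[length(rows) + 1L]] <- data.frame(
          n_added = k, pcrit = pc,
          ne = estimate_ne(gm, pc, ci = FALSE)$ne_hat)
      }
      if (k == kmax && k > 0L) {
        truth <- n_individuals(focal) + seq_len(k)
        cl <- iterative_clean(gm, threshold, max_iter)
        first <- if (length(cl$removed_by_iteration) >= 1L)
          cl$removed_by_iteration[[1]] else integer(0)
        cleaning <- list(n_contaminants = k,
                         removed_first_iteration = sum(first %in% truth),
                         removed_total = sum(cl$removed %in% truth),
                         iterations = cl$iterations)
      }
    }
    list(grid = do.call(rbind, rows), cleaning = cleaning)
  })
}

#' Sampling distribution of LD-Ne estimates
#'
#' Replicates the short-horizon design used to characterise the estimator:
#' each replicate founds a population of size `n` from the spectrum,
#' breeds it for four individual-based generations (enough for the drift
#' LD to reach its asymptote), samples `s` genotypes, applies the
#' missingness pattern and estimates Ne at each `pcrit`.
#'
#' @param spectrum an [afreq_table()] founder spectrum.
#' @param n population size.
#' @param reps number of replicates (default 200).
#' @param s sample size (capped at `n`).
#' @param pcrits thresholds at which to estimate Ne.
#' @param missingness a [missingness_pattern()] or `NULL`.
#' @param pool_below,pool_above histogram pooling bounds used in the
#'   summary (estimates below/above these, or negative, are tallied as
#'   tail mass).
#' @param seed integer seed.
#' @return A list: `estimates` (data frame `rep`, `pcrit`, `ne`) and
#'   `summary` (per pcrit: SD of estimates, fraction negative, fraction
#'   pooled into each tail).
#' @export
run_ne_distribution <- function(spectrum, n, reps = 200L, s = 5413L,
                                pcrits = c(0.05, 0.01, 0.001, 0.0001),
                                missingness = default_missingness(),
                                pool_below = -20000, pool_above = 40000,
                                seed = NULL) {
  s <- min(s, n)
  with_seed(seed, {
    rows <- list()
    for (rep_i in seq_len(reps)) {
      gm <- evolve_population(spectrum, n, 4L, ib_generations = 4L)
      smp <- sample_individuals(gm, s)
      if (!is.null(missingness)) smp <- apply_missingness(smp, missingness)
      for (pc in pcrits) {
        rows[[length(rows) + 1L]] <- data.frame(
          rep = rep_i, pcrit = pc,
          ne = estimate_ne(smp, pc, ci = FALSE)$ne_hat)
      }
    }
    est <- do.call(rbind, rows)
    summ <- do.call(rbind, lapply(split(est, est$pcrit), function(d) {
      data.frame(pcrit = d$pcrit[1], sd = stats::sd(d$ne),
                 frac_negative = mean(d$ne < 0),
                 frac_low_tail = mean(d$ne < pool_below),
                 frac_high_tail = mean(d$ne > pool_above | d$ne < 0))
    }))
    rownames(summ) <- NULL
    list(estimates = est, summary = summ)
  })
}
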