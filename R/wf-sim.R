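#' Found a population from an allele-frequency table
#'
#' Creates `n` diploid genotypes by drawing, per locus, two alleles
#' independently from the given frequencies (random union of gametes, so
#' the founders are in Hardy-Weinberg and linkage equilibrium in
#' expectation).
#'
#' @param freqs an [afreq_table()].
#' @param n number of individuals (even, >= 4, for downstream breeding).
#' @param seed integer seed.
#' @return A [genotype_matrix()] with no missing calls.
#' @export
found_population <- function(freqs, n, seed = NULL) {
  stopifnot(inherits(freqs, "afreq_table"))
  L <- length(freqs$loci)
  with_seed(seed, {
    a1 <- matrix(0L, n, L)
    a2 <- matrix(0L, n, L)
    for (l in seq_len(L)) {
      f <- freqs$freqs[[l]]
      codes <- as.integer(names(f))
      a1[, l] <- codes[sample.int(length(f), n, replace = TRUE, prob = f)]
      a2[, l] <- codes[sample.int(length(f), n, replace = TRUE, prob = f)]
    }
    genotype_matrix(a1, a2, locus_names = freqs$loci)
  })
}

#' Advance a population through discrete Wright-Fisher generations
#'
#' Non-overlapping generations with separate sexes: in each generation the
#' first half of the population is female and the second half male, each
#' offspring draws a mother and a father independently with replacement,
#' and each parent transmits one uniformly chosen allele per locus.  Loci
#' are unlinked (independent transmission) and population size stays
#' constant.
#'
#' @param gm a fully typed [genotype_matrix()] with an even number of
#'   individuals (>= 4).
#' @param g number of generations to advance (>= 0).
#' @param seed integer seed.
#' @return The generation-`g` [genotype_matrix()].
#' @export
advance_generations <- function(gm, g, seed = NULL) {
  n <- n_individuals(gm)
  L <- n_loci(gm)
  if (n %% 2L != 0L || n < 4L) stop("population size must be even and >= 4")
  if (anyNA(gm$a1)) stop("breeding population must have no missing calls")
  if (g < 0L) stop("g must be >= 0")
  if (g == 0L) return(gm)
  a1 <- gm$a1
  a2 <- gm$a2
  half <- n %/% 2L
  with_seed(seed, {
    for (gen in seq_len(g)) {
      mom <- sample.int(half, n, replace = TRUE)
      dad <- half + sample.int(half, n, replace = TRUE)
      pick_m <- matrix(stats::runif(n * L) < 0.5, n, L)
      pick_d <- matrix(stats::runif(n * L) < 0.5, n, L)
      new1 <- a1[mom, , drop = FALSE]
      alt1 <- a2[mom, , drop = FALSE]
      new1[pick_m] <- alt1[pick_m]
      new2 <- a1[dad, , drop = FALSE]
      alt2 <- a2[dad, , drop = FALSE]
      new2[pick_d] <- alt2[pick_d]
      a1 <- new1
      a2 <- new2
    }
    genotype_matrix(a1, a2, locus_names = gm$locus_names)
  })
}

#' Allele-frequency drift (fast path for long horizons)
#'
#' Propagates allele frequencies through `g` generations of pure drift by
#' multinomial resampling of `2n` allele copies per locus per generation --
#' the frequency-level equivalent of the individual-based model, suitable
#' for divergence horizons of hundreds to thousands of generations.
#' Alleles lost along the way stay lost (and are dropped from the table).
#'
#' @param freqs an [afreq_table()].
#' @param n diploid population size.
#' @param g number of generations (>= 0; `g = 0` returns the input).
#' @param seed integer seed.
#' @return A drifted [afreq_table()].
#' @export
drift_frequencies <- function(freqs, n, g, seed = NULL) {
  stopifnot(inherits(freqs, "afreq_table"))
  if (g < 0L) stop("g must be >= 0")
  if (g == 0L) return(freqs)
  two_n <- 2L * as.integer(n)
  with_seed(seed, {
    out <- vector("list", length(freqs$loci))
    for (l in seq_along(freqs$loci)) {
      f <- freqs$freqs[[l]]
      counts <- stats::rmultinom(1, two_n, f)[, 1]
      if (g > 1L) for (gen in 2:g) {
        counts <- stats::rmultinom(1, two_n, counts)[, 1]
      }
      keep <- counts > 0L
      f2 <- counts[keep] / two_n
      names(f2) <- names(f)[keep]
      out[[l]] <- f2
    }
    names(out) <- freqs$loci
    afreq_table(freqs$loci, out)
  })
}

#' Evolve a population over a divergence horizon (hybrid path)
#'
#' Runs `generations` total generations of Wright-Fisher evolution at size
#' `n`: the first `generations - ib_generations` as fast allele-frequency
#' drift ([drift_frequencies()]), then a random-union founding and
#' `ib_generations - 1` individual-based generations, so that the sampled
#' generation carries the asymptotic drift LD (reached within about four
#' individual-based generations) while long horizons stay cheap.  For
#' `generations <= ib_generations` the run is fully individual-based
#' (founding + `generations - 1` breeding rounds).
#'
#' @inheritParams drift_frequencies
#' @param generations total generations (>= 1).
#' @param ib_generations terminal individual-based generations (>= 4;
#'   default 8).
#' @return A [genotype_matrix()] of the final generation.
#' @export
evolve_population <- function(freqs, n, generations, ib_generations = 8L,
                              seed = NULL) {
  if (generations < 1L) stop("generations must be >= 1")
  if (ib_generations < 4L)
    stop("at least 4 terminal individual-based generations are required")
  with_seed(seed, {
    ib <- min(ib_generations, generations)
    f <- drift_frequencies(freqs, n, generations - ib)
    gm <- found_population(f, n)
    advance_generations(gm, ib - 1L)
  })
}

#' Sample individuals from a population
#'
#' Simple random sample without replacement ("plan 2": sampled individuals
#' are not removed from the breeding pool, which matters for interpretation
#' but not mechanics).
#'
#' @param gm a [genotype_matrix()].
#' @param s sample size (<= number of individuals).
#' @param seed integer seed.
#' @return A [genotype_matrix()] of `s` individuals.
#' @export
sample_individuals <- function(gm, s, seed = NULL) {
  n <- n_individuals(gm)
  if (s > n) stop("cannot sample ", s, " individuals from ", n)
  with_seed(seed, gm[sample.int(n, s)])
}

#' Replace focal genotypes with immigrants
#'
#' Replaces `m` uniformly chosen individuals of the focal sample with `m`
#' uniformly chosen donor individuals (both without replacement),
#' emulating non-interbreeding immigrants or contaminants in a field
#' sample.  The positions of the planted immigrants are recorded for
#' detection scoring.
#'
#' @param focal,donor [genotype_matrix()] objects with the same locus panel.
#' @param m number of immigrants (0 <= m <= min of the two sample sizes).
#' @param seed integer seed.
#' @return The mixed `genotype_matrix` with attribute `"immigrant_idx"`
#'   (row positions of the planted immigrants).
#' @export
mix_immigrants <- function(focal, donor, m, seed = NULL) {
  if (!identical(focal$locus_names, donor$locus_names))
    stop("focal and donor samples must share the same locus panel")
  nf <- n_individuals(focal)
  nd <- n_individuals(donor)
  if (m < 0L || m > nf || m > nd)
    stop("m must lie in [0, min(focal, donor) sample size]")
  if (m == 0L) {
    attr(focal, "immigrant_idx") <- integer(0)
    return(focal)
  }
  with_seed(seed, {
    at <- sample.int(nf, m)
    from <- sample.int(nd, m)
    a1 <- focal$a1
    a2 <- focal$a2
    a1[at, ] <- donor$a1[from, , drop = FALSE]
    a2[at, ] <- donor$a2[from, , drop = FALSE]
    ids <- focal$individual_ids
    ids[at] <- paste0("imm_", donor$individual_ids[from])
    out <- genotype_matrix(a1, a2, ids, focal$locus_names, focal$pop)
    attr(out, "immigrant_idx") <- sort(at)
    out
  })
}
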