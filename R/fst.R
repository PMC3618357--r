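#' Pairwise Weir-Cockerham FST (theta)
#'
#' Multi-allelic variance-components estimator of differentiation between
#' two population samples: for every allele at every shared locus the
#' among-population (a), among-individual (b) and within-individual (c)
#' components are computed from sample sizes, allele frequencies and
#' heterozygote frequencies, summed over alleles and loci, and combined as
#' `theta = sum(a) / sum(a + b + c)`.  Individuals missing a locus are
#' excluded at that locus only.  Slightly negative values are possible for
#' undifferentiated samples.
#'
#' @param gm_a,gm_b [genotype_matrix()] objects sharing the same locus
#'   panel, each with >= 2 individuals.
#' @return The theta estimate.
#' @export
pairwise_fst <- function(gm_a, gm_b) {
  if (!identical(gm_a$locus_names, gm_b$locus_names))
    stop("the two samples must share the same locus panel")
  if (n_individuals(gm_a) < 2L || n_individuals(gm_b) < 2L)
    stop("each sample needs at least 2 individuals")
  num <- 0
  den <- 0
  r <- 2
  for (l in seq_len(n_loci(gm_a))) {
    ta <- which(!is.na(gm_a$a1[, l]))
    tb <- which(!is.na(gm_b$a1[, l]))
    n1 <- length(ta)
    n2 <- length(tb)
    if (n1 < 2L || n2 < 2L) next
    alleles <- sort(unique(c(gm_a$a1[ta, l], gm_a$a2[ta, l],
                             gm_b$a1[tb, l], gm_b$a2[tb, l])))
    if (length(alleles) < 2L) next
    dos <- function(gm, rows, u) {
      (gm$a1[rows, l] == u) + (gm$a2[rows, l] == u)
    }
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    for (u in alleles) {
      d1 <- dos(gm_a, ta, u)
      d2 <- dos(gm_b, tb, u)
      p1 <- sum(d1) / (2 * n1)
      p2 <- sum(d2) / (2 * n2)
      h1 <- mean(d1 == 1L)
      h2 <- mean(d2 == 1L)
      pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
      s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
      hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  if (den == 0) stop("no shared polymorphic locus: theta undefined")
  num / den
}
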