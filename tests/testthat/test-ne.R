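test_that("expected_sample_r2 evaluates and decreases in S", {
  expect_equal(expected_sample_r2(100), 0.010319)
  expect_equal(expected_sample_r2(5413), 1 / 5413 + 3.19 / 5413^2)
  s <- c(10, 100, 1000, 1e6)
  expect_true(all(diff(expected_sample_r2(s)) < 0))
  expect_error(expected_sample_r2(1), ">= 2")
})

test_that("the quadratic Ne solution round-trips the drift expectation", {
  ne <- c(50, 137, 1000, 25000, 1e6)
  rp <- 1 / (3 * ne) - 0.69 / ne^2
  back <- ne_from_r2prime(rp)
  expect_lt(max(abs(back - ne) / ne), 1e-9)
  # direct evaluations
  expect_equal(ne_from_r2prime(1 / 3000 - 0.69 / 1e6), 1000, tolerance = 1e-6)
  expect_equal(ne_from_r2prime(-0.001), -335.39, tolerance = 1e-4)
  expect_identical(ne_from_r2prime(0), Inf)
})

test_that("Ne is strictly decreasing in r2' with sensible extremes", {
  rp <- sort(c(10^seq(-6, -2, length.out = 30)))
  ne <- ne_from_r2prime(rp)
  expect_true(all(diff(ne) < 0))
  expect_gt(ne[1], 1e5)
  # beyond the radicand range the first-order fallback kicks in with warning
  expect_warning(out <- ne_from_r2prime(0.05), "first-order")
  expect_equal(as.numeric(out), 1 / (3 * 0.05))
})

test_that("jackknife SE matches the closed-form oracle on assigned values", {
  # 21 locus pairs (7 loci) with hand-assigned r2 and equal weights
  set.seed(61)
  r2 <- runif(21, 4e-4, 6e-4)
  ld <- structure(list(
    mean_r2 = mean(r2), s_eff = 5000,
    e_sample_r2 = expected_sample_r2(5000),
    r2_prime = mean(r2) - expected_sample_r2(5000), pcrit = 0.01,
    n_pairs_retained = 21L, n_undefined = 0L,
    pair_table = data.frame(locus_a = "a", locus_b = "b", n_ab = 5000,
                            n_retained = 1L, sum_w = 5000, sum_wr2 = 5000 * r2)),
    class = "ld_summary")
  jk <- jackknife_ci(ld)
  # oracle: literal delete-one recomputation with plain means
  theta <- sapply(1:21, function(i) mean(r2[-i]))
  se <- sqrt(20 / 21 * sum((theta - mean(theta))^2))
  expect_equal(jk$se_r2, se, tolerance = 1e-12)
  expect_equal(jk$r2p_upper, ld$r2_prime + qnorm(0.975) * se, tolerance = 1e-12)
  # bounds bracket the point estimate
  ne <- ne_from_r2prime(ld$r2_prime)
  expect_lt(jk$ci_lower, ne)
  expect_true(jk$ci_upper > ne || is.infinite(jk$ci_upper))
})

test_that("degenerate jackknives collapse or flag as specified", {
  mk <- function(r2, n_pairs) {
    structure(list(mean_r2 = mean(r2), s_eff = 300,
                   e_sample_r2 = expected_sample_r2(300),
                   r2_prime = mean(r2) - expected_sample_r2(300), pcrit = 0,
                   n_pairs_retained = n_pairs, n_undefined = 0L,
                   pair_table = data.frame(n_ab = 300, n_retained = 1L,
                                           sum_w = 300, sum_wr2 = 300 * r2)),
              class = "ld_summary")
  }
  # identical r2 values: SE 0, CI collapses to the point estimate
  ld <- mk(rep(4e-3, 10), 10L)
  jk <- jackknife_ci(ld)
  expect_equal(jk$se_r2, 0)
  expect_equal(jk$ci_lower, jk$ci_upper)
  expect_equal(jk$ci_lower, ne_from_r2prime(ld$r2_prime))
  # fewer than 3 locus pairs: undefined
  expect_false(jackknife_ci(mk(rep(4e-3, 2), 2L))$defined)
  # non-positive lower r2' bound maps to infinite upper Ne
  ld2 <- mk(c(3e-3, 3.2e-3, 3.6e-3, 3.4e-3), 4L)  # r2' near 0
  jk2 <- jackknife_ci(ld2)
  expect_true(is.infinite(jk2$ci_upper))
})

test_that("duplicating every individual changes Ne only via the S-correction", {
  set.seed(71)
  gm <- random_gm(60, 4, alleles_per_locus = 5L)
  dup <- genotype_matrix(rbind(gm$a1, gm$a1), rbind(gm$a2, gm$a2))
  e1 <- estimate_ne(gm, 0.02, ci = FALSE)
  e2 <- estimate_ne(dup, 0.02, ci = FALSE)
  expect_equal(e2$mean_r2, e1$mean_r2, tolerance = 1e-12)
  expect_equal(e2$s_eff, 2 * e1$s_eff)
  expect_equal(e2$ne_hat,
               ne_from_r2prime(e1$mean_r2 - expected_sample_r2(2 * e1$s_eff)),
               tolerance = 1e-9)
})

test_that("random union at effectively infinite N gives negative or huge Ne", {
  set.seed(81)
  nes <- replicate(12, estimate_ne(found_population(toy_spectrum(), 300L),
                                   0.02, ci = FALSE)$ne_hat)
  expect_gt(mean(nes < 0 | nes > 3000), 0.5)
})

test_that("harmonic mean aggregates positive estimates and reports exclusions", {
  expect_equal(as.numeric(harmonic_mean_ne(c(1000, 1000, 1000))), 1000)
  expect_equal(as.numeric(harmonic_mean_ne(c(500, 2000))), 800)
  hm <- harmonic_mean_ne(c(1000, -5000))
  expect_equal(as.numeric(hm), 1000)
  expect_equal(attr(hm, "n_excluded"), 1L)
  expect_error(harmonic_mean_ne(c(-1, -2)), "no positive")
})
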