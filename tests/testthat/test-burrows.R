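test_that("genotype-class counts classify forced cases correctly", {
  # one individual (j,j) x (k,k)
  gm <- genotype_matrix(matrix(c(1L, 2L), 1, 2), matrix(c(1L, 2L), 1, 2))
  cnt <- count_genotype_pairs(gm, 1, 2, 1, 2)
  expect_equal(cnt[c("x_jjkk", "x_jjkh", "x_jhkk", "x_jhkh")],
               list(x_jjkk = 1L, x_jjkh = 0L, x_jhkk = 0L, x_jhkh = 0L),
               ignore_attr = TRUE)
  expect_equal(cnt$n_ab, 1L)
  # one double heterozygote (j,j*) x (k,k*)
  gm2 <- genotype_matrix(matrix(c(1L, 2L), 1, 2), matrix(c(3L, 4L), 1, 2))
  cnt2 <- count_genotype_pairs(gm2, 1, 2, 1, 2)
  expect_equal(cnt2$x_jhkh, 1L)
  expect_equal(cnt2$x_jjkk + cnt2$x_jjkh + cnt2$x_jhkk, 0L)
  expect_error(count_genotype_pairs(gm, 1, 1, 1, 1), "differ")
})

test_that("composite pair frequency matches forced cases and divisor choice", {
  hom <- genotype_matrix(matrix(c(1L, 2L), 4, 2, byrow = TRUE),
                         matrix(c(1L, 2L), 4, 2, byrow = TRUE))
  cnt <- count_genotype_pairs(hom, 1, 2, 1, 2)
  expect_equal(composite_pair_freq(cnt), 2)             # all (j,j)x(k,k)
  expect_equal(composite_pair_freq(cnt, "gametes"), 1)  # literal 2n divisor
  het <- genotype_matrix(matrix(c(1L, 2L), 4, 2, byrow = TRUE),
                         matrix(c(3L, 4L), 4, 2, byrow = TRUE))
  expect_equal(composite_pair_freq(count_genotype_pairs(het, 1, 2, 1, 2)), 0.5)
  # allele pair never co-carried (allele 9 absent from locus 2)
  expect_equal(composite_pair_freq(count_genotype_pairs(het, 1, 2, 1, 9)), 0)
})

test_that("mixed hand-listed genotypes match the class-enumeration oracle", {
  set.seed(11)
  for (rep_i in 1:20) {
    gm <- random_gm(6, 2, alleles_per_locus = 3L)
    for (j in 1:3) for (k in 1:3) {
      cnt <- count_genotype_pairs(gm, 1, 2, j, k)
      # oracle: per-individual composite contributions
      expected <- 0
      for (i in 1:6) {
        nj <- sum(c(gm$a1[i, 1], gm$a2[i, 1]) == j)
        nk <- sum(c(gm$a1[i, 2], gm$a2[i, 2]) == k)
        expected <- expected +
          2 * (nj == 2 && nk == 2) + (nj == 2 && nk == 1) +
          (nj == 1 && nk == 2) + 0.5 * (nj == 1 && nk == 1)
      }
      expect_equal(composite_pair_freq(cnt) * cnt$n_ab, expected)
    }
  }
})

test_that("burrows_r2 reproduces the perfect-association hand calculation", {
  # (1,1)x(1,1) and (2,2)x(2,2): p = 0.5, D = 0.25, delta = 0.5, r2 = 1
  gm <- genotype_matrix(matrix(c(1L, 2L, 1L, 2L), 2, 2),
                        matrix(c(1L, 2L, 1L, 2L), 2, 2))
  r <- burrows_r2(gm, 1, 2, 1, 1)
  expect_equal(r$p_a, 0.5)
  expect_equal(r$d_a, 0.25)
  expect_equal(r$delta, 0.5)
  expect_equal(r$r2, 1)
})

test_that("monomorphic loci give zero disequilibrium and undefined pairs", {
  gm <- genotype_matrix(cbind(rep(1L, 5), c(1L, 2L, 1L, 2L, 1L)),
                        cbind(rep(1L, 5), c(2L, 2L, 1L, 2L, 2L)))
  r <- burrows_r2(gm, 1, 2, 1, 2)
  expect_equal(r$delta, 0)
  expect_false(r$defined)
  # a summary over only monomorphic-vs-polymorphic pairs has nothing to keep
  expect_error(mean_r2(gm, 0), "retained|monomorphic|Pcrit")
})

test_that("vectorised r2 equals the brute-force oracle to 1e-12", {
  set.seed(21)
  for (rep_i in 1:8) {
    gm <- random_gm(25, 3, alleles_per_locus = 4L,
                    miss_prob = ifelse(rep_i %% 2 == 0, 0.2, 0))
    tab <- ld_pair_table(gm, 0)
    for (q in seq_len(nrow(tab))) {
      ia <- match(tab$locus_a[q], gm$locus_names)
      ib <- match(tab$locus_b[q], gm$locus_names)
      expected <- oracle_r2(gm, ia, ib, tab$allele_j[q], tab$allele_k[q])
      if (is.na(expected)) {
        expect_true(is.na(tab$r2[q]) || !tab$retained[q])
      } else {
        expect_equal(tab$r2[q], expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("mean_r2 equals the exhaustive oracle on a 3-locus dataset", {
  set.seed(31)
  gm <- random_gm(40, 3, alleles_per_locus = 5L, miss_prob = 0.15)
  for (pc in c(0, 0.05)) {
    got <- mean_r2(gm, pc)
    want <- oracle_mean_r2(gm, pc)
    expect_equal(got$mean_r2, want$mean_r2, tolerance = 1e-12)
    expect_equal(got$s_eff, want$s_eff, tolerance = 1e-12)
  }
})

test_that("Pcrit filtering excludes below-threshold alleles, keeps equals", {
  # allele 3 at locus 1 has frequency 0.005 (1 copy in 100 genotypes);
  # locus 2 segregates in Hardy-Weinberg-ish proportions
  a1 <- cbind(rep(1L, 100), rep(c(1L, 1L, 2L, 1L), 25))
  a2 <- cbind(c(rep(2L, 99), 3L), rep(c(1L, 2L, 2L, 2L), 25))
  gm <- genotype_matrix(a1, a2)
  tab <- ld_pair_table(gm, 0.01)
  expect_true(all(!tab$retained[tab$allele_j == 3]))
  # pcrit = 0 retains every observed allele pair with a defined r2
  tab0 <- ld_pair_table(gm, 0)
  expect_equal(sum(tab0$retained), sum(!is.na(tab0$r2)))
  expect_true(any(tab0$retained[tab0$allele_j == 3]))
  # frequency exactly equal to pcrit is retained
  gmx <- genotype_matrix(cbind(c(1L, 1L, 1L, 2L), rep(1L, 4)),
                         cbind(c(1L, 1L, 2L, 2L), c(1L, 1L, 2L, 2L)))
  # p(allele 2 at locus 1) = 3/8
  tabx <- ld_pair_table(gmx, 3 / 8)
  expect_true(any(tabx$retained[tabx$allele_j == 2]))
})

test_that("permuting individual order leaves LD summaries unchanged", {
  set.seed(41)
  gm <- random_gm(50, 4, alleles_per_locus = 5L, miss_prob = 0.1)
  perm <- sample(50)
  s1 <- mean_r2(gm, 0.02)
  s2 <- mean_r2(gm[perm], 0.02)
  expect_equal(s1$mean_r2, s2$mean_r2, tolerance = 1e-12)
  expect_equal(s1$s_eff, s2$s_eff)
  expect_equal(s1$n_pairs_retained, s2$n_pairs_retained)
})

test_that("under independence the mean r2 approaches the sampling term", {
  set.seed(51)
  S <- 400L
  spec <- toy_spectrum()
  m <- replicate(30, mean_r2(found_population(spec, S), 0.02)$mean_r2)
  expect_equal(mean(m), expected_sample_r2(S), tolerance = 0.1)
})
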