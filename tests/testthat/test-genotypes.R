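test_that("genotype_matrix validates and normalises calls", {
  gm <- genotype_matrix(matrix(c(3L, 1L), 1, 2), matrix(c(1L, 2L), 1, 2))
  # unordered pairs stored as (min, max)
  expect_equal(gm$a1[1, ], c(1L, 1L))
  expect_equal(gm$a2[1, ], c(3L, 2L))
  expect_error(genotype_matrix(matrix(1L, 1, 1), matrix(NA_integer_, 1, 1)),
               "half-missing")
  expect_error(genotype_matrix(matrix(0L, 1, 1), matrix(1L, 1, 1)), "positive")
  expect_error(genotype_matrix(matrix(1L, 2, 2), matrix(1L, 2, 2),
                               locus_names = c("a", "a")), "unique")
})

test_that("allele_frequencies counts typed calls per locus", {
  gm <- genotype_matrix(matrix(c(1L, 1L, 2L), 3, 1),
                        matrix(c(1L, 2L, 2L), 3, 1))
  f <- allele_frequencies(gm)
  expect_equal(as.numeric(f$freqs[[1]]), c(0.5, 0.5))
  # with one missing individual: (1,1), (1,2), NA -> p1 = 0.75, S_L = 2
  gm2 <- genotype_matrix(matrix(c(1L, 1L, NA), 3, 1),
                         matrix(c(1L, 2L, NA), 3, 1))
  f2 <- allele_frequencies(gm2)
  expect_equal(as.numeric(f2$freqs[[1]]), c(0.75, 0.25))
  expect_equal(f2$n_typed, 2L)
  # monomorphic
  gm3 <- genotype_matrix(matrix(5L, 4, 1), matrix(5L, 4, 1))
  expect_equal(as.numeric(allele_frequencies(gm3)$freqs[[1]]), 1)
  # all-missing locus errors by name
  gm4 <- genotype_matrix(cbind(c(1L, 1L), c(NA, NA)), cbind(c(1L, 2L), c(NA, NA)),
                         locus_names = c("ok", "empty"))
  expect_error(allele_frequencies(gm4), "empty")
})

test_that("allele frequencies sum to 1 on random matrices", {
  set.seed(42)
  for (i in 1:10) {
    gm <- random_gm(30, 4, alleles_per_locus = 6L, miss_prob = 0.2)
    f <- allele_frequencies(gm)
    expect_true(all(abs(sapply(f$freqs, sum) - 1) < 1e-12))
  }
})

test_that("Genepop round trip preserves codes, missingness and order", {
  set.seed(7)
  for (width in c(2L, 3L)) {
    gm <- random_gm(12, 5, alleles_per_locus = if (width == 2L) 9L else 40L,
                    miss_prob = 0.15)
    path <- withr::local_tempfile(fileext = ".gen")
    write_genepop(gm, path, width = width)
    back <- read_genepop(path)
    expect_identical(back$a1, gm$a1)
    expect_identical(back$a2, gm$a2)
    expect_identical(back$individual_ids, gm$individual_ids)
    expect_identical(back$locus_names, gm$locus_names)
    # bit-stable output
    path2 <- withr::local_tempfile(fileext = ".gen")
    write_genepop(gm, path2, width = width)
    expect_identical(readLines(path), readLines(path2))
  }
})

test_that("hand-written Genepop file parses, including missing sentinel", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy file", "locA", "locB", "Pop",
               "fish1 ,  001002 003003",
               "fish2 ,  000000 004005"), path)
  gm <- read_genepop(path)
  expect_equal(n_loci(gm), 2L)
  expect_true(is.na(gm$a1[2, 1]) && is.na(gm$a2[2, 1]))
  expect_equal(sum(is.na(gm$a1)), 1L)
  expect_equal(gm$a1[1, ], c(1L, 3L))
  expect_equal(gm$a2[2, 2], 5L)
})

test_that("a seven-locus panel file loads with L = 7", {
  panel <- default_spectrum_spec()$locus
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("panel", panel, "Pop",
               paste("ind1 , ", paste(rep("001002", 7), collapse = " "))), path)
  gm <- read_genepop(path)
  expect_equal(length(gm$locus_names), 7L)
  expect_identical(gm$locus_names, panel)
})

test_that("the shipped toy Genepop fixture loads with two population blocks", {
  path <- system.file("extdata", "toy_mackerel.gen", package = "ldnetools")
  gm <- read_genepop(path)
  expect_equal(n_individuals(gm), 12L)
  expect_equal(n_loci(gm), 7L)
  expect_equal(unname(table(gm$pop)[c("pop_1", "pop_2")]), c(10L, 2L),
               ignore_attr = TRUE)
  expect_equal(sum(is.na(gm$a1)), 3L)   # three "000000" calls
  f <- allele_frequencies(gm)
  expect_true(all(abs(sapply(f$freqs, sum) - 1) < 1e-12))
})

test_that("Genepop writing rejects bad inputs; parse errors name the line", {
  gm <- genotype_matrix(matrix(1500L, 2, 2), matrix(1500L, 2, 2))
  expect_error(write_genepop(gm, tempfile(), width = 3L), "does not fit")
  expect_error(write_genepop(genotype_matrix(matrix(integer(0), 0, 2),
                                             matrix(integer(0), 0, 2)),
                             tempfile()), "empty")
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("bad", "locA", "locB", "Pop", "f1 ,  001002 0030"), path)
  expect_error(read_genepop(path), "line 5")
})

test_that("spectrum synthesis honours its marginal constraints", {
  spec <- default_spectrum_spec()
  tab <- synthesize_spectrum(spec, seed = 11)
  for (l in seq_len(nrow(spec))) {
    f <- tab$freqs[[l]]
    expect_length(f, spec$na[l])
    expect_equal(max(f), spec$max_freq[l], tolerance = 1e-9)
    expect_lt(abs(sum(f <= 0.01) / spec$na[l] - spec$low_frac[l]), 0.10 + 1e-9)
    expect_true(all(f > 0) && abs(sum(f) - 1) < 1e-12)
  }
  # ~65% of alleles across loci at frequency <= 0.01
  allf <- unlist(tab$freqs)
  expect_lt(abs(mean(allf <= 0.01) - 0.65), 0.10)
  # bit-reproducible under a fixed seed
  expect_identical(tab$freqs, synthesize_spectrum(spec, seed = 11)$freqs)
  # forced two-allele spectrum
  expect_equal(as.numeric(synthesize_spectrum(
    spectrum_spec("x", 2, 0.5, 0), seed = 1)$freqs[[1]]), c(0.5, 0.5))
  # infeasible: maximum below 1/na
  expect_error(spectrum_spec("x", 4, 0.2, 0), "infeasible")
})

test_that("missingness modes behave as specified", {
  gm <- random_gm(400, 7, seed = 3)
  # all-zero probabilities: identity
  p0 <- missingness_pattern("probability", probs = rep(0, 7))
  expect_identical(apply_missingness(gm, p0, seed = 1)$a1, gm$a1)
  # forced donor mask: every individual missing exactly locus 3
  mask <- matrix(FALSE, 1, 7); mask[1, 3] <- TRUE
  pd <- missingness_pattern("donor", donor_masks = mask)
  out <- apply_missingness(gm, pd, seed = 2)
  expect_true(all(is.na(out$a1[, 3])))
  expect_true(all(!is.na(out$a1[, -3])))
  # donor masks leaving < 2 typed loci are rejected at construction
  bad <- matrix(TRUE, 1, 7); bad[1, 1] <- FALSE
  expect_error(missingness_pattern("donor", donor_masks = bad), "2 typed")
})

test_that("default missingness reproduces the 71/12/10/7 typed-locus profile", {
  gm <- random_gm(6000, 7, seed = 4)
  out <- apply_missingness(gm, default_missingness(), seed = 5)
  tab <- attr(out, "typed_count_table")
  frac <- as.numeric(tab[as.character(7:4)]) / 6000
  expect_lt(max(abs(frac - c(0.71, 0.12, 0.10, 0.07))), 0.02)
  expect_true(all(rowSums(!is.na(out$a1)) >= 2))
})
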