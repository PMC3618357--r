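Package: ldnetools
Title: Linkage-Disequilibrium Effective Population Size with Outlier Genotype Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates effective population size (Ne) from the linkage
    disequilibrium among unlinked microsatellite loci in large diploid
    genotype samples. Implements the Burrows composite-disequilibrium
    correlation for unphased multi-allelic genotypes, allele-frequency
    (Pcrit) filtering, the bias-corrected quadratic Ne estimator with
    delete-one-locus-pair jackknife confidence intervals, a forward
    Wright-Fisher genotype simulator with a fast allele-frequency drift
    path for long divergence horizons, multi-allelic Weir-Cockerham FST,
    and an iterative correspondence-analysis algorithm that detects and
    removes outlier genotypes (immigrants or non-target species) which
    otherwise bias LD-based Ne estimates downward. Includes Genepop
    input/output and scripted drivers for divergence, contamination and
    sampling-distribution experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
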