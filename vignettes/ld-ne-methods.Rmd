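---
title: "LD-based Ne estimation with outlier screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-based Ne estimation with outlier screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `ldnetools`, the
choices made where the methodology left room, and what the simulation suite
does and does not establish about real data.

## The drift signal in two-locus associations

In a closed, randomly mating diploid population of effective size $N_e$,
drift generates association between alleles at unlinked loci. For sampled,
unphased genotypes the association between allele $j$ at locus $A$ and
allele $k$ at locus $B$ is measured by the Burrows composite
disequilibrium
$$\hat\Delta_{jk} = \tilde P(A_jB_k) - 2\hat p_{A_j}\hat p_{B_k},$$
where $\tilde P(A_jB_k)$ is the per-individual composite count of $j$–$k$
pairings: homozygote–homozygote carriers contribute 2, a single
heterozygous locus contributes 1, and the double heterozygote contributes
$1/2$ (its two phases are equally likely, and only one pairs $j$ with $k$).
The correlation is normalised as a phi coefficient with variances corrected
for departure from Hardy–Weinberg proportions,
$$\hat r_{jk} = \frac{\hat\Delta_{jk}}
{\sqrt{[\hat p_{A_j}(1-\hat p_{A_j})+\hat D_{A_j}]
       [\hat p_{B_k}(1-\hat p_{B_k})+\hat D_{B_k}]}},
\qquad \hat D_{A_j} = f(A_jA_j) - \hat p_{A_j}^2 .$$

The mean of $\hat r^2_{jk}$ over allele pairs at all $L(L-1)/2$ locus pairs
exceeds zero even without drift because $S$ sampled individuals carry
sampling noise; the expected contribution is $E[\hat r^2_{\rm sample}] =
1/S + 3.19/S^2$. Subtracting it leaves the drift component
$\hat r^{2\prime}$, which the drift expectation
$r^{2\prime} = \tfrac{1}{3N_e} - \tfrac{0.69}{N_e^2}$ inverts to
$$\hat N_e = \frac{1/3 + \sqrt{1/9 - 2.76\,\hat r^{2\prime}}}{2\hat r^{2\prime}}.$$

Two numerical notes on this inversion:

* **Sign of the radicand.** Only the minus form is consistent with the
  drift expectation above: substituting
  $r^{2\prime} = 1/(3N_e) - 0.69/N_e^2$ must return $N_e$ exactly, and the
  package tests this round trip to $10^{-9}$ relative error over
  $N_e \in [50, 10^6]$. (With a plus sign the quadratic does not
  round-trip.)
* **Degenerate regions.** $\hat r^{2\prime} \le 0$ means the observed
  association is at or below sampling noise; the estimate is negative (or
  infinite at exactly zero) and is reported as such — a negative $\hat N_e$
  is the method's signal that $N_e$ is too large for the sample, not an
  error. If $\hat r^{2\prime} > 1/24.84$ the radicand goes negative (LD far
  stronger than the second-order drift model); the first-order estimate
  $1/(3\hat r^{2\prime})$ is returned with a warning flag.

### Pcrit filtering, weighting and missing data

Alleles with sample frequency below a threshold `pcrit` are excluded from
the average (a frequency exactly equal to the threshold is retained,
reading "below the threshold" literally). Rare alleles make
$\hat r^2_{jk}$ a noisy, upward-biased ratio statistic, and the
`run_ne_distribution()` driver reproduces the practical consequence: the
replicate SD of $\hat N_e$ is smallest for `pcrit` between 0.001 and 0.01
under the package's default panel.

With missing data, every pairwise quantity — allele frequencies for
filtering, homozygote frequencies, $\hat\Delta$ — is recomputed on the
subset of individuals jointly typed at the two loci ($n_{AB}$ of them), so
each pairwise estimator is internally consistent. Each retained
$\hat r^2_{jk}$ is weighted by its $n_{AB}$; the effective sample size
$S_{\rm eff}$ entering the sampling correction is the harmonic mean of
$n_{AB}$ over retained locus pairs. These two choices are deliberately the
simplest that degrade gracefully under the package's missingness model; a
Monte-Carlo test confirms that under independent loci (random union of
gametes) the filtered, weighted mean $\hat r^2$ matches
$1/S_{\rm eff} + 3.19/S^2_{\rm eff}$ within Monte-Carlo error, so the
correction is centred.

One definitional point: if the composite count were divided by the total
number of *gametes* ($2n_{AB}$) rather than individuals, the disequilibrium
of a monomorphic double-homozygote sample would be $-1$ instead of 0 and
$\hat\Delta$ would not vanish under independence. The package therefore
uses the per-individual divisor (range $[0,2]$), which is also the
composite formulation used by LDNE-family software; the literal
gamete-count divisor is available in `composite_pair_freq()` behind the
`divisor` argument for comparison.

### Confidence intervals

The interval is a delete-one-locus-pair jackknife on the weighted mean
$\hat r^2$: a normal-approximation interval on $\hat r^{2\prime}$ mapped
through the (monotone decreasing) $N_e$ transform, so the lower $N_e$ bound
comes from the upper $r^{2\prime}$ bound, and a non-positive lower
$r^{2\prime}$ bound maps to an infinite upper bound. The method name
"jackknife" admits several constructions; the normal-approximation form was
chosen for transparency and is exercised against a closed-form oracle in
the tests. A chi-square-on-degrees-of-freedom variant could be added
without changing the interface. With fewer than three locus pairs the
interval is flagged undefined.

## The synthetic data model

### Allele-frequency spectra

`default_spectrum_spec()` encodes the package's reference panel: seven
microsatellite loci with 24–38 alleles, per-locus maximum frequencies from
0.127 to 0.735, and band counts that put roughly 65% of all alleles at
frequency $\le 0.01$ — the spectrum structure of a large Spanish mackerel
genotyping campaign (5413 individuals). `synthesize_spectrum()` pins the
head allele at the target maximum, lays out the remaining alleles on
banded geometric-decay series (above 0.10, 0.01–0.10, 0.001–0.01, below
0.001), balances band masses so the vector sums to one, perturbs the tail
with a Dirichlet jitter (concentration 400, i.e. roughly 5–10% coefficient
of variation on common alleles), and rejects draws until the realised
maximum is exact and the fraction of alleles $\le 0.01$ is within 10
percentage points of target. Only the marginal band structure is known, so
the within-band shape (geometric decay) is a modelling choice; it
reproduces the qualitative rare-allele dominance that drives the `pcrit`
phenomena.

### Missing data

The reference missingness model is *correlated across loci*: 71% of
individuals typed at all 7 loci, 12% at 6, 10% at 5 and 7% at 4. A model
with independent per-locus knockouts at the per-locus rates implied by the
panel's locus sample sizes ($1 - S_L/5413$) cannot reproduce that profile —
it would put only ~57% of individuals in the fully-typed class — which is
why `default_missingness()` draws the *number* of missing loci per
individual from (0.71, 0.12, 0.10, 0.07) and then selects *which* loci
proportionally to the per-locus rates. The expected number of missing loci
per individual under the typed-count distribution (0.53) happens to equal
the sum of the per-locus rates, so both sets of published marginals are
matched simultaneously. Independent-Bernoulli and donor-mask-resampling
modes remain available in `missingness_pattern()`.

### The Wright–Fisher simulator

`found_population()` draws genotypes by random union of gametes from a
frequency table; `advance_generations()` runs discrete non-overlapping
generations with positionally assigned separate sexes (first half female),
each offspring drawing a mother and father independently with replacement
and receiving one uniformly chosen allele per parent per locus. Loci are
unlinked and neutral; there is no mutation, selection, age structure or
linkage — deliberately a pure-drift null model, so that divergence between
replicate populations is governed by $1-(1-\tfrac{1}{2N})^g$ alone (the
test suite checks the drift variance and the FST calibration against this
closed form).

Long divergence horizons use a hybrid path (`evolve_population()`): the
first $g - 8$ generations run as per-locus multinomial resampling of $2N$
allele copies (`drift_frequencies()`, distributionally equivalent for
allele frequencies and orders of magnitude faster), then a random-union
founding and 8 individual-based generations. Between-locus LD needs only
about four generations to reach its drift asymptote, so 8 terminal
individual-based generations reproduce the sampled generation's LD
distribution; a Kolmogorov–Smirnov property test compares the hybrid and
fully individual-based $\hat r^2$ distributions.

Short-horizon designs (the sampling-distribution study) use founding plus
three breeding rounds — four discrete generations — matching the
generation at which the estimator is meant to be applied.

## The correspondence-analysis outlier screen

Outlier genotypes — non-target species, or immigrants from populations
diverged by drift — inject association between otherwise independent loci
(mixture LD) and bias $\hat N_e$ downward. The screen:

1. build the individuals × alleles dosage table (0/1/2 copies; missing
   loci contribute zero dosage and simply lower that row's mass);
2. run classical correspondence analysis (centre by row/column masses,
   scale by inverse square-root masses, SVD) and take the **row principal
   coordinates** on the first two axes;
3. flag individuals with $|PC1| + |PC2| > 2$;
4. remove them, rebuild the allele columns from the survivors, and repeat
   until no individual is flagged or 10 iterations have run.

Three conventions deserve comment, because the outlier rule is stated as a
fixed threshold rather than a quantile:

* **Coordinate scaling.** Row principal coordinates are singular-value- and
  mass-scaled; in a many-allele dosage CA the per-axis inertia is small, so
  the central cluster sits well inside $\pm 1$ and the fixed threshold of 2
  isolates genuinely displaced individuals. Standardised row scores would
  put typical individuals at unit scale and flag thousands.
* **Combining the axes.** A signed sum $PC1 + PC2$ would depend on the
  arbitrary sign of each singular vector; "furthest from the central
  cluster" is a distance, so the package uses $|PC1|+|PC2|$ (L1), with L2
  as an option. Axis signs are additionally normalised (largest-magnitude
  column loading positive) so results are reproducible across LAPACK
  implementations.
* **Indicator coding.** Dosage (0/1/2) rather than binary
  presence/absence; dosage preserves homozygote/heterozygote information
  and keeps column sums equal to allele counts (tested as a conservation
  law).

Behaviourally, the first axes capture the largest coherent displacement in
the sample. A block of immigrants sharing donor-private alleles forms such
a direction and is removed in the first iteration or two; later iterations
peel individuals carrying extremely rare alleles (each rare-allele column
is nearly its own axis), which is why even pure samples lose a small
fraction (of the order of 1%) before the loop stops — the no-immigrant
arms of the test suite check that this moves the harmonic-mean $\hat N_e$
by well under 10%. For species-level contaminants the package's surrogate
is an independently synthesized spectrum with allele identities permuted
per locus and two loci wholly non-amplifying; such contaminants are
essentially all removed in the first iteration.

## FST

Differentiation is measured by the Weir–Cockerham variance-components
estimator $\theta$: per allele per locus the among-population,
among-individual and within-individual components are computed from sample
sizes, allele frequencies and heterozygote frequencies, summed over alleles
and loci, and combined as a ratio of sums. Individuals missing a locus drop
out at that locus only; $\theta$ is computed on the genotype *samples*
(5413 per population) rather than the full populations — at these sample
sizes the difference is negligible.

## Study designs and problem sizes

The experiment drivers default to the reference study conditions:
populations of $N = 10{,}000$ (sampling $S = 5413$), 10 replicate
populations per divergence horizon, 100 immigrants per mixture, `pcrit`
thresholds 0 and 0.01. The acceptance script runs all 90 directed mixtures
at the 2000-generation horizon; the test suite uses 12 mixtures and
smaller Monte-Carlo replicate counts (e.g. 24–60 replicates for the
sampling-distribution and recovery properties), sizes chosen so the whole
suite runs in about a minute while keeping Monte-Carlo error within the
stated test tolerances. The sampling-distribution driver caps the sample
at $S = \min(S, N)$, since plan-2 sampling without replacement cannot draw
more individuals than the population holds.

## What the simulations do and do not show

The synthetic generator reproduces the *marginal* allele-frequency bands,
the maximum frequencies, and the typed-locus profile of a real
microsatellite campaign. It does not model genotyping error, null alleles,
allelic dropout, mutation (relevant over thousands of generations),
selection, linked loci, overlapping generations, or correlated missingness
beyond the typed-count structure. Consequently, passing the suite shows
that the estimator stack and the outlier screen behave correctly under the
pure-drift model that underlies the $N_e$ theory — it does not certify
performance under marker artefacts, and on real data the outlier screen
should be treated as a pre-filter whose removals deserve inspection, not as
a classifier with known error rates. The CA threshold of 2 is a
calibration to this panel's scale (thousands of individuals, hundreds of
alleles); panels with very different dimensions may need a different
threshold, which is why both the threshold and the norm are arguments.
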