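---
title: "Methods: dosage-based association scans for low-frequency and common variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-based association scans for low-frequency and common variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosagescan)
```

# The scientific question

Low-pass whole-genome sequencing and imputation deliver genotype *dosages* —
expected minor-allele counts in $[0, 2]$ — for millions of variants, roughly
half of them low frequency (minor allele frequency, MAF, below 5%). Two
questions recur when such data are used to map quantitative trait loci
(cis-acting expression QTLs, circulating biomarkers):

1. How many low-frequency variants have per-allele effects large enough to
   explain as much phenotypic variance as detectable common variants?
2. Are apparent common-variant associations actually driven by a
   low-frequency variant in partial linkage disequilibrium (LD) with them?

`dosagescan` implements the full decision pipeline around those questions —
phenotype normalization, single-variant association tests on dosages,
multiplicity correction via LD binning, conditional classification against
the opposing allele-frequency bin, call-set concordance QC, and the analytic
power model — together with a synthetic cohort generator so that every stage
can be exercised and validated without access to individual-level human data.

# The variance-power-effect model

For an additive biallelic variant with allele frequency $p$ and standardized
per-allele effect $\beta$ (phenotype-SD units), the fraction of phenotypic
variance explained is

$$ V = \beta^2 \cdot 2p(1-p), $$

so $\beta = \sqrt{V / (2p(1-p))}$ (`effect_from_variance()`). Detection
power depends on the data only through $V$ and the sample size $n$: the
association test's noncentrality is $n V / (1 - V)$. `analytic_power()`
evaluates, by default, the exact small-sample form — a noncentral
$F(1, n-2)$ (equivalently noncentral $t$) with that noncentrality against
the two-sided critical value at level $\alpha$. Two large-sample chi-square
conventions ($\mathrm{ncp} = nV$ and $nV/(1-V)$ against the 1-df chi-square
quantile) are provided for comparison via the `convention` argument; the
exact $F$ form was adopted as the default because it tracks the reference
power grid for $n = 450$, $\alpha = 10^{-6}$ noticeably more closely
(within about 0.01 everywhere, versus up to 0.03 for either chi-square
form). A direct consequence of the model, visible in `power_grid()`, is
that power is constant across MAF at fixed $V$, while the required effect
size grows as frequency falls: a 1% variant must carry a ~1.6 SD effect to
explain the 5% of variance a 20% variant explains at 0.4 SD.

`empirical_power()` is the simulation cross-check: each replicate draws
Hardy-Weinberg genotypes, builds the trait, and runs the package's own OLS
test. The per-allele effect is calibrated to the replicate's *realized*
genotype variance so that the variance explained — the quantity the
analytic model is parameterized by — is held exactly at $V$. At low MAF the
realized genotype variance fluctuates substantially between cohorts of 450;
calibrating to it makes the simulation estimate the same estimand as the
analytic formula rather than a mixture over realized $V$.

# Phenotype preparation

`prepare_phenotype()` implements double inverse-normalization with
covariate residualization: rank-based inverse-normal transform
(`inverse_normal()`), least-squares residualization on covariates, then a
second inverse-normal transform. The first transform tames the heavy tails
of raw intensities before a linear adjustment; the second restores exact
marginal normality for the association tests. The second transform is
monotone in the residuals, so it never reorders them.

Numerical choices, made where the procedure is conventionally
underspecified:

* **Quantile offset**: Blom's $c = 3/8$, i.e.
  $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ — the standard choice in
  genetics pipelines; configurable via `offset`.
* **Ties**: average ranks — deterministic and input-order independent.
* Fewer than 3 non-missing values, or all-equal values, are errors;
  missing values propagate untouched.

A caveat the tests make explicit: residualizing on the *transformed* scale
removes covariate correlation exactly only when covariate effects are
(close to) linear on that scale. When effects are multiplicative on the raw
intensity scale — the usual behaviour of array intensities — the log/rank
scale is the linear one and residual correlations after the second
transform are negligible (|r| well under 0.02 at $n = 450$). Strong
covariate effects that are additive on a heavily skewed raw scale would
leave nonlinear traces no rank transform can remove.

# Association engine

`test_variant_ols()` is simple linear regression of the prepared phenotype
on the dosage, used as-is (never rounded to hard calls); p-values are
two-sided from $t_{n-2}$. `scan_cis()` tests every retained variant within
±1 Mb of the trait's transcription start site (`cis_window()`), and
`scan_genome()` drops the windowing. The index variant is the minimum-p
test; ties break by larger |effect|, then lower position.

For cohorts retaining close relatives, `fit_null_mixed()` fits the
one-variance-component mixed model $y \sim N(\mu,\ \sigma^2_g K +
\sigma^2_e I)$ by restricted maximum likelihood using the spectral
decomposition of the kinship matrix $K$: after rotating by the
eigenvectors, the REML criterion is profiled over
$\lambda = \sigma^2_g/\sigma^2_e$ on a log grid ($\log\lambda \in [-8, 8]$,
33 points) refined by `optimize()`. `test_variant_mixed()` then performs a
weighted regression of rotated phenotype on rotated dosage with the
variance components fixed at their null estimates — the standard
two-stage approximation that makes a genome scan one cheap regression per
variant. Degenerate cases are defined, not left to chance: a flat REML
criterion (identity kinship — the scale cancels) or a boundary minimum
pins $\lambda$ at 0, flagged `boundary`, and the mixed test then reproduces
OLS exactly.

Kinship follows the coefficient-of-relationship convention: self 1, full
sibs 0.5, unrelated 0. Only relative scale matters — a rescaled $K$ changes
the fitted $\lambda$ but not the test.

# Multiplicity: independent tests and thresholds

Dosage-scale LD is squared Pearson correlation (`pairwise_r2()`),
allele-flip invariant, with null expectation $\approx 1/(n-1)$.
`ldselect_bins()` is the greedy tag-variant binning used to count
independent variants: repeatedly pick the unbinned variant with the most
unbinned companions at $r^2 >$ threshold (default 0.8), bin it with those
companions, remove them. Ties on companion count break by lowest genomic
position; each variant joins exactly one bin. The companion counts are
maintained incrementally as bins are removed, which leaves the greedy
result identical to naive recomputation (the tests compare against a
literal brute-force implementation) while scaling to thousands of variants
per window.

`estimate_independent_per_window()` draws 2 Mb windows (one per chromosome,
or `n_windows` from a single simulated chromosome, flagged), applies the
inclusion filters (imputation quality strictly > 0.7, MAC ≥ 4), and
averages bin counts — overall and separately within the low-frequency and
common strata. `effective_tests()` turns a per-window count into a total:
`cis` mode multiplies by the number of phenotypes (one window each);
`genome` mode first scales by ~1500 (the number of 2 Mb windows in a
genome). The Bonferroni threshold is 0.05 divided by that total, and
`estimate_fdr()` gives the standard plug-in estimate
(threshold × independent tests) / observed hits.

# Conditional classification

For each index signal, the question is whether the *opposing* MAF bin
(common vs low frequency) explains it. `condition_on_opposing_bin()`
implements both stages: conditioning on the single best opposing-bin
variant in the region, or (`mode = "full"`) on all opposing-bin variants
with $p < 10^{-4}$ thinned to mutual $r^2 < 0.2$ by PLINK-style greedy
clumping (`clump()`). Classification of the index's conditional p-value
(`classify_signal()`):

* `fully_explained` — all evidence lost, conditional $p > 0.05$;
* `retained` — still below the discovery threshold;
* `attenuated` — in between.

Guard rails: conditioning on self is structurally impossible; an index in
near-perfect LD with a conditioner ($r^2 > 0.999$) is reported
`collinear` and excluded from counts; conditioners collinear among
themselves are dropped with a warning. `compare_detection()` asks, for
signals discovered in one dosage set, whether a proxy within ±250 kb
reaches the strict or a loose ($10^{-4}$) threshold in another call set —
the comparison used to judge imputation-only analyses against sequencing.

# Concordance QC

`site_overlap()` compares a query call set against a deep-sequenced truth
set after three ordered filters: an excluded-region mask, removal of sites
where any truth genotype was called below a depth threshold, and removal of
non-biallelic sites; it reports the true-positive proportion and
false-negative rate. `genotype_concordance()` tabulates the 3×3
(truth × query) genotype matrix at shared sites; non-reference concordance
drops the hom-ref/hom-ref cell from numerator and denominator. Genotype
classes come from rounding dosages to the nearest hard call, matching how
comparisons against array genotypes are done. `detect_sample_swaps()`
applies the chip-concordance rule — keep strictly above 0.98; concordance
in [0.4, 0.6] is labelled swap-like, since a mislabelled sample agrees with
its array data at roughly the rate two random individuals share genotypes.
`titv_ratio()` is the usual transition/transversion call-set summary.

# The synthetic cohort generator

The generator exists so that every downstream stage has a truth to be
tested against; it emulates the *outputs* of a low-pass
sequencing/imputation pipeline, not the pipeline itself.

* **Frequency spectrum** (`afs_spec()`): a mixture — with probability
  `p_low` (default 0.5) a Beta(1, 30) draw truncated to [0.004, 0.05),
  otherwise uniform on [0.05, 0.5]. The default emits roughly equal
  numbers of low-frequency and common variants, matching deep call sets in
  which the two classes are of comparable size.
* **LD structure** (`simulate_haplotype_pool()`): variants sit on blocks
  (default 50 kb); within a block each haplotype carries one of
  `n_founders` (default 8) founder lineages, and variant alleles are laid
  out along a per-block founder order with binomial thinning of the last,
  partially-carrying founder, so any target frequency is reachable while
  variants in a block share carriers and correlate. Founder assignments
  are redrawn across block boundaries, so cross-block $r^2$ is near zero.
  A per-variant reshuffle probability (default 0.3) adds allelic
  heterogeneity within blocks.
* **Cohorts** (`sample_cohort()`): haplotype pairs drawn without
  replacement; optional sibships share four parental haplotypes per pair.
  The kinship matrix returned is the pedigree expectation, which is what a
  mixed model consumes.
* **Dosage degradation** (`degrade_to_dosages()`): for target quality $q$,
  genotypes are shrunk toward their Hardy-Weinberg mean by $q$ plus
  Gaussian noise of variance $q(1-q)\,\mathrm{var}(g)$ — giving both a
  variance-ratio quality and a squared dosage-genotype correlation of
  $\approx q$ — then clipped to $[0, 2]$. Because clipping removes
  variance and biases the mean at rare sites, a short fixed-point
  iteration rescales deviations and re-centers until the realized
  variance ratio (same estimator as `estimate_imputation_quality()`)
  matches the target; calibration holds to within ~0.03 for variants with
  MAF ≥ 1%. No MAF dependence is imposed on quality by default; pass a
  per-variant vector to create one.
* **Traits** (`simulate_traits()`): each trait is
  $\beta\,(g - \bar g) + \sum_j \gamma_j c_j + \varepsilon$ with $\beta$
  set from the truth table at the causal variant's cohort frequency,
  standardized covariates contributing $\sum \gamma_j^2$, and noise
  absorbing the remainder so total variance is 1 in expectation.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: coalescent allele-frequency/LD coupling, read
depth-dependent genotype error, population structure beyond declared
sibships, batch structure in the dosages, indel sequence realism (indels
are labels only), and in-probe polymorphism artefacts of expression
arrays.

# Problem sizes and numerical choices in the test-suite

The validation suite runs entirely on synthetic data at sizes chosen to
keep a full run around half a minute while leaving sampling error well
inside the asserted tolerances: cohorts of 450 (the canonical expression
cohort size) for power, type-I and classification checks; 10,000
permutations for type-I error; 5000/2000 replicates for the power
simulation cross-checks; 100 planted and 100 control loci for the
conditional classifier; variance bookkeeping at n = 20,000. Two
sensitivity-driven choices deserve note. First, heritability recovery with
a sib-pairs-only kinship is intrinsically noisy (single-cohort SE ≈ 0.13
at n = 600, since only the 0.5 off-diagonals are informative), so the
recovery check judges the mean REML estimate over 12 replicate cohorts
against the ±0.1 band rather than a single draw. Second, the planted
tagging architecture uses a low-frequency causal (MAF 3%, V = 0.10) nested
on a 10% common haplotype background ($r^2 \approx 0.28$), the regime the
conditional procedure is designed to resolve.

# Known limitations

* The mixed model carries exactly one genetic variance component; no
  environment/household components, no multiple kinships.
* Conditional analysis implements the two-stage opposing-bin procedure,
  not general stepwise forward selection.
* `estimate_fdr()` is the plug-in expected-false-positive ratio; at a
  threshold of $10^{-6}$ with ~31.7M independent tests and 1314 hits it
  returns ≈ 2.4%, which is the formula's answer — looser folklore values
  for the same inputs are not reproduced.
* Multi-allelic sites are read and flagged but never split; genotype
  likelihoods are out of scope.
* VCF writing emits a minimal DS/RSQ representation, not a full FORMAT
  complement.
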