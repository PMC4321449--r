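Package: dosagescan
Title: Association Scans on Genotype Dosages for Low-Frequency and Common Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing the contribution of low-frequency
    (MAF < 5%) and common (MAF >= 5%) variants to quantitative traits using
    genotype dosages from low-pass sequencing or imputation. Provides a
    synthetic cohort generator with block-structured linkage disequilibrium
    and calibrated dosage quality, dosage VCF input/output with the standard
    variant inclusion filters (biallelic, MAC >= 4, imputation r-squared
    > 0.7), call-set concordance quality control, double inverse-normal
    phenotype transformation with covariate residualization, cis and
    genome-wide single-variant association tests (ordinary least squares and
    a one-variance-component mixed model for related samples), estimation of
    the effective number of independent tests by greedy LD binning,
    conditional classification of signals against the opposing allele
    frequency bin, and analytic power calculations for quantitative trait
    loci.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
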