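# xwasmeta

Sex-stratified X-chromosome-wide association meta-analysis from GWAS
summary statistics.

The X chromosome is routinely excluded from GWAS meta-analyses because it
violates autosomal assumptions: males are hemizygous, imputation software
disagree on dosage coding (male 0/1 vs 0/2, female 0/0.5/1 vs 0/1/2),
effects can differ between the sexes, and escape from X-inactivation (XCI)
inflates apparent female effects under the standard 0/1/2 coding.
`xwasmeta` is for analysts running multi-study, multi-ancestry,
sex-stratified X-chromosome scans of quantitative traits (its worked
examples use kidney traits: eGFR and serum urate) who need the whole chain
as tested, composable functions:

- **Harmonization & QC** — allele alignment and per-study filters
  (AF deviation > 20%, info < 0.5, MAC < 6, MAF < 0.01, pseudoautosomal
  regions), inference of the X dosage coding from the characteristic
  standard-error ratio pattern (`infer_dosage_coding()`), harmonization to
  male 0/2 / female 0/1/2.
- **Meta-analysis** — per-study sex combination, genomic control
  (λ = median(z²)/0.4549, SE inflation by √λ when λ > 1), fixed-effect
  inverse-variance pooling with Q/I², sample-size-weighted MAF/info
  eligibility filters, variance explained r² = β²/(β² + N·se²), and
  ancestry meta-regression on externally supplied axes.
- **Loci & interactions** — iterative 1-Mb locus definition with merging,
  sex-difference testing with cross-sex correlation
  z = (β_m − β_f)/√(se_m² + se_f² − 2ρ·se_m·se_f), the XCI sensitivity
  analysis (halve female β and SE, re-test), and sex-pattern
  classification (male/female-specific, sex-differential).
- **Fine-mapping & colocalization** — stepwise conditional selection of
  independent signals against an LD reference (collinearity 0.9), 99%
  credible sets from Wakefield approximate Bayes factors with an
  empirically estimated prior SD, and five-hypothesis Bayesian
  colocalization (H0–H4) for male-vs-female, trait-vs-trait and
  trait-vs-eQTL pairs.
- **Enrichment & gene prioritization** — exact binomial enrichment of
  androgen-response-element (ARE) annotations against empirical
  backgrounds, and a nine-criteria ordered rule engine for candidate
  genes.
- **Simulator** — `simulate_panel()` draws multi-study sex-stratified
  summary statistics directly (multivariate-normal z-scores within LD
  blocks, Balding–Nichols ancestry frequencies, configurable dosage
  codings and XCI escape) with full ground truth, so every stage is
  testable against known answers.

## Worked example

Published index-variant statistics for the 23 X-chromosomal kidney-trait
loci ship with the package:

```r
library(xwasmeta)

tab <- xchr_index_variants()
ua  <- tab[tab$trait == "UA", ]
sum(ua$var_explained_pct)
#> UA aggregate variance explained: 0.066%

# ARE enrichment at the six sex-interaction loci, against the empirical
# backgrounds (tier<=3 AREs near 49% of random variants; proven
# ARE-driven regulation for 4.3%)
binomial_enrichment(6, 6, 0.49)   # 0.014
binomial_enrichment(2, 6, 0.043)  # 0.025
```

The seven urate loci jointly explain 0.066% of trait variance, and
finding AREs at all six sex-interaction loci (p = 0.014), with proven
ARE-driven regulation at two (p = 0.025), is more than chance expects.

A full pipeline run on a simulated ten-study panel with one planted
male-specific, one female-specific and one sex-differential locus:

```r
cfg <- sim_config(
  n_studies = 10, n_male = 15000, n_female = 15000,
  n_variants = 900, n_auto_variants = 200, ld_decay = 0.7,
  freq_range = c(0.2, 0.8), info_range = c(0.85, 1), seed = 8,
  causal_spec = data.frame(index = c(100, 450, 800),
                           beta_male   = c(0.03, 0,    0.02),
                           beta_female = c(0,    0.03, 0.04)),
  coding = data.frame(study = paste0("study", 1:10),
                      male   = rep(c("0/2", "0/1"), 5),
                      female = rep(c("0/1/2", "0/0.5/1"), each = 5)))
panel <- simulate_panel(cfg)
run_xwas_pipeline(panel, min_studies = 10)
#> sex-stratified X-chromosome meta-analysis
#>   variants meta-analyzed: 897  rho: 0.056
#>   loci: 3
#>   locus index_rsid      index_p stratum p_interaction
#> 1     1     vX0100 1.664531e-10 overall  2.108897e-11
#> 2     2     vX0800 1.092842e-30 overall  5.161278e-03
#> 3     3     vX0450 5.158221e-17  female  3.446700e-15
#>                          pattern
#> 1                  male-specific
#> 2 sex-differential-female-larger
#> 3                female-specific
```

Despite the four different dosage codings injected across the ten
studies, all three planted loci are recovered with the correct labels:
the female-specific hit surfaces only through the sex-stratified
supplement (stratum `female`), and the sex-differential locus — whose
female effect is exactly twice the male one — is additionally flagged
`xci_dependent`, because halving female effects (the no-inactivation
sensitivity model) makes its interaction vanish.

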