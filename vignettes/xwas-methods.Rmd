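---
title: "Sex-stratified X-chromosome meta-analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified X-chromosome meta-analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xwasmeta)
```

# Why the X chromosome needs its own pipeline

Genome-wide association meta-analyses routinely drop the X chromosome
because it breaks the assumptions autosomal tooling relies on. Males are
hemizygous, so a male genotype carries 0 or 1 copies of an allele while a
female carries 0, 1 or 2; under the standard working model of complete,
random X-chromosome inactivation (XCI), one of the two female copies is
silenced in each cell, and the conventional dosage harmonization codes
males 0/2 against females 0/1/2 so that one dosage unit has the same
expected expression consequence in both sexes. Imputation software
differ in which coding they emit (male 0/1 vs 0/2, female 0/0.5/1 vs
0/1/2), effects on the X may genuinely differ between the sexes, and
genes can *escape* inactivation, in which case the female effects are
over-estimated under the 0/1/2 coding.

`xwasmeta` implements the analysis chain a consortium needs to run a
sex-stratified X-chromosome-wide association study from per-study
summary statistics: per-study QC and dosage harmonization, genomic
control, fixed-effect meta-analysis, locus definition, sex-interaction
testing with an XCI sensitivity analysis, conditional signal selection
and credible sets, Bayesian colocalization, cross-trait classification,
androgen-response-element (ARE) enrichment and a gene-prioritization
rule engine. A summary-statistic simulator generates panels with known
ground truth so every stage can be validated end to end.

# The simulator: what it emulates and what it does not

`simulate_panel()` draws summary statistics directly rather than
simulating genotypes. Within an LD block with correlation matrix $R$
(AR(1): $r_{ij} = \rho^{|i-j|}$), the per-study, per-sex z-score vector
is multivariate normal with mean $R\lambda$ and covariance $R$. The
non-centrality of variant $j$ with allele frequency $f$ is

$$\lambda_{m,j} = \beta_{m,j}\,\sqrt{N_m \cdot 4f(1-f)}/\sigma,\qquad
  \lambda_{f,j} = \beta_{f,j}\, e \,\sqrt{N_f \cdot 2f(1-f)}/\sigma,$$

with $4f(1-f)$ the male dosage variance under 0/2 coding, $2f(1-f)$ the
female one under 0/1/2, $e \in [1,2]$ the XCI-escape multiplier (1 =
complete random inactivation, 2 = complete escape) and $\sigma$ the
residual SD. Standard errors are $\sigma/\sqrt{N\,\mathrm{Var}(g)}$ and
betas are recovered as $z \cdot se$, so null z-scores are exactly
standard normal — null distributions of every downstream test are exact
by construction, which is the reason for simulating at the
summary-statistic level in the first place. Ancestry allele frequencies
follow a Balding–Nichols Beta draw around the ancestral frequency with
a per-ancestry divergence parameter. Study-specific dosage codings are
then injected by rescaling beta and SE by 2 where the dosage range
halves; $z$ is invariant under this rescaling.

Female per-allele effects under full XCI are taken equal to male
per-dosage-unit effects on the harmonized coding; escape is a single
multiplier applied to the female non-centrality. Binary traits are not
simulated separately: all pipeline stages operate on beta/SE and are
trait-agnostic.

What the simulator deliberately does **not** model: imputation error
correlated with frequency (info scores are drawn independently,
uniform on a configurable interval, default $[0.6, 1]$), relatedness,
case-control liability scales, and genotype-level artefacts. Passing
tests therefore demonstrate the statistical machinery is correct under
the stated sampling model, not that real consortium data are free of
artefacts the QC stage exists to catch.

Defaults follow what a desk-scale emulation of a large consortium
needs: 10 studies (the minimum for locus discovery), 1000 samples per
sex per study, Fst-like divergence 0.02, LD decay 0.9, ancestral
frequencies uniform on $(0.05, 0.95)$. The per-study distributions of
sample size, info and ancestry divergence are not dictated by any
reference dataset; they are configuration, not inference.

# Harmonization and QC

`qc_filter_study()` applies the standard per-study filters in a fixed
order — allele-frequency deviation from the reference $> 0.20$ (after
allele alignment, flipping beta and EAF where effect/other alleles are
swapped), info $< 0.5$, minor allele count $< 6$ (computed as
$2N\min(f, 1-f)$ on the 0/1/2 scale, without sex-specific treatment),
MAF $< 0.01$, and pseudoautosomal-region membership. Removal thresholds
are strict inequalities, so values exactly at a threshold are kept. The
retained set is order-insensitive; only the report's attribution of a
multiply-failing variant (to the first failing filter) depends on the
order. PAR intervals default to hg19 PAR1 X:60,001–2,699,520 and PAR2
X:154,931,044–155,260,560 and are configurable.

`infer_dosage_coding()` exploits the fact that a mis-declared dosage
coding rescales standard errors by 2: for each sex,
$s = \mathrm{median}\bigl(se\sqrt{N \cdot 2f(1-f)}\bigr)$ estimates the
residual SD under autosomal 0/1/2 coding, and the ratio of $s$ on the X
to $s$ on autosomes has expectation $1/\sqrt2$ (male 0/2), $\sqrt2$
(male 0/1), 1 (female 0/1/2) or 2 (female 0/0.5/1). Classification is
nearest-expected on the log scale. The middle third of the log-gap is
declared *ambiguous* and `harmonize_coding()` refuses to act on it:
ambiguity is something to resolve with the study analysts, not to
guess. The median (rather than the mean) makes the proxy robust to the
handful of genuinely associated variants. On simulated studies with
1000 samples per sex and 200 variants per chromosome group the
classification is essentially always correct (the test suite requires
at least 99% over 100 studies).

# Meta-analysis

Sexes are combined per study by fixed-effect inverse-variance
weighting, after excluding variants whose male and female allele
frequencies differ by more than 0.20. Genomic control uses
$\lambda_{GC} = \mathrm{median}(z^2)/0.4549364$, estimated on
X-chromosome variants only; when $\lambda > 1$ the SEs are inflated by
$\sqrt\lambda$ (equivalent to dividing the chi-square by $\lambda$,
chosen so betas stay interpretable) — first within each sex stratum,
then again on the per-study combined results. Genomic control is
applied per study only, not to the cross-study meta results; a config
switch is unnecessary because `genomic_control()` composes with any
record set.

Cross-study pooling is again inverse-variance fixed-effect, with
Cochran's $Q$ and $I^2$. A variant is *discovery-eligible* when at
least 10 studies contribute, $I^2 \le 95\%$, sample-size-weighted MAF
$\ge 0.02$ and weighted info $\ge 0.8$; ineligible variants are
retained (flagged) so interaction and cross-trait lookups remain
possible. Two-sided p-values come from the normal approximation
throughout, matching Wald-based per-study estimates. Note an interplay
worth knowing when simulating: with the simulator's default info range
$[0.6, 1]$ the weighted info of a 10-study panel sits at the 0.8
eligibility boundary, so roughly half of all variants are randomly
ineligible — emulating a well-imputed panel requires an info range
above 0.8, as the end-to-end tests do with $[0.85, 1]$.

Variance explained is $r^2 = \beta^2/(\beta^2 + N\,se^2)$. The
cross-ancestry meta-regression regresses per-study betas on externally
supplied ancestry axes by weighted least squares with weights $1/se^2$;
ancestry-correlated heterogeneity is the Wald chi-square on the axis
coefficients (df = number of axes, default 3), association the joint
chi-square on all coefficients (df = axes + 1), and residual
heterogeneity the weighted residual sum of squares. This is a
large-sample equivalent of the dedicated meta-regression software's
likelihood machinery, adopted deliberately: identical asymptotic
behavior, and testable at desk scale (the suite checks null calibration
of the heterogeneity p by simulation and power against an
effect-direction flip between ancestries).

# Loci, interactions and the XCI sensitivity analysis

`define_loci()` iterates: take the smallest-p genome-wide significant
variant ($p < 5\times10^{-8}$), assign the 1-Mb window centered on it,
remove covered variants, repeat; then merge overlapping windows to a
fixpoint, keeping the lower-p index. Interval arithmetic treats exactly
touching intervals as overlapping (the conservative reading) and equal-p
ties break by smaller position for determinism. Loci are defined on the
overall stratum first and supplemented by sex-stratified loci whose
index variant is not covered by any overall locus; supplementation is
applied after overall merging, one stratum at a time.

The sex-difference test standardizes the difference of the sex-specific
estimates by
$\sqrt{se_m^2 + se_f^2 - 2\rho\,se_m se_f}$, where $\rho$ is a single
chromosome-wide Spearman correlation of the paired beta estimates —
male and female meta-statistics share study designs, so their test
statistics are positively correlated; ignoring $\rho > 0$ is
conservative. When too few variants are available to estimate $\rho$,
trait-typical defaults are provided (0.16 eGFR-like, 0.12 urate-like).

The XCI sensitivity analysis halves female betas *and* SEs before
re-testing: under complete escape from inactivation the 0/1/2 coding
over-estimates female effects by exactly 2, so a "female-larger"
interaction that survives halving is robust to the XCI model, while one
that vanishes ($\beta_f = 2\beta_m$ cancels algebraically) is
XCI-model-dependent and flagged as such.

Pattern classification is explicit config rather than narrative:
*sex-specific* requires a significant interaction, one sex genome-wide
significant and the other not even nominally associated
($p \ge 0.05$); *sex-differential* requires a significant interaction
with both sexes nominally associated, labelled by the larger absolute
effect. No multiple-testing correction is applied to the interaction
tests by default (the tested index variants are few). One consequence
of the nominal-0.05 "not associated" arm: a truly null other-sex effect
still reaches $p < 0.05$ in 5% of datasets, in which case a planted
sex-specific locus is labelled sex-differential; this is a property of
the rule, not of the implementation, and is visible occasionally in the
end-to-end simulation.

# Fine-mapping and colocalization

`stepwise_select()` performs conditional-and-joint style forward
selection on the standardized scale: conditional z of candidate $i$
given selected set $S$ is
$(z_i - R_{iS}R_{SS}^{-1}z_S)/\sqrt{1 - R_{iS}R_{SS}^{-1}R_{Si}}$,
candidates with $r^2 \ge 0.9$ to the selected set are never tested, and
selection stops when no conditional p clears $5\times10^{-8}$. This is
an approximation of the frequency- and N-aware genotype-based
implementations: on one locus with comparable per-variant sample sizes
the standardized form is equivalent, and the suite verifies it against
an independent joint-solve oracle and against individual-level joint
regression on simulated data.

Credible sets use Wakefield approximate Bayes factors
$\log ABF = \tfrac12\log\frac{V}{V+W} + \frac{z^2}{2}\frac{W}{V+W}$
with an *empirical* prior: $W^{1/2}$ is the central-95% range of the
locus' effect estimates divided by $2\times1.959964$, floored at
$10^{-6}$. The percentile-difference-to-SD conversion is the natural
reading of an empirically calibrated prior and is configurable; for a
normal spread it recovers the SD exactly. Posteriors are normalized
ABFs (one causal variant per signal assumed); the 99% set is the
minimal PP-descending prefix, with boundary ties included, and
conditional statistics are used for secondary signals. Because the ABF
shrinks with $V/(V+W)$, the smallest-p variant need not top the PP
ranking when SEs (i.e. allele frequencies) differ — a documented,
intended behavior.

`coloc_abf()` enumerates the five-hypothesis posterior (H0 none, H1/H2
one trait only, H3 two distinct causal variants, H4 shared causal
variant) from the two traits' ABFs with priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$, accumulating configuration
sums by log-sum-exp for numerical stability. Per-trait prior SDs
default to the locus-empirical estimate. Decision thresholds are applied
by callers: 0.75 as "sufficient support", 0.5 for the deliberately
conservative cross-trait overlap rule (overlap when $r^2 \ge 0.1$ *or*
$PP(H4) \ge 0.5$).

# Enrichment and gene prioritization

ARE enrichment is an exact binomial upper tail $P(X \ge k)$ against an
empirically estimated background rate (fraction of 1000 randomly
annotated variants carrying the annotation). Against the tier-three ARE
background of 49% and the proven-ARE-regulation background of 4.3%, six
of six and two of six annotated sex-interaction loci give one-sided p
of 0.014 and 0.025 (two significant figures; rounding is presentation
only). The gene-prioritization engine applies nine ordered criteria
(credible-set missense with CADD > 10 and PP > 1%, kidney-tissue eQTL
colocalization, kidney-gene eQTL colocalization in any tissue, ARE near
a kidney gene — sex-interaction loci only —, kidney gene near a
high-CADD credible-set variant, kidney gene nearby, any eQTL
colocalization, any gene near a high-CADD variant, proximity fallback)
with a ±250 kb annotation window; annotations and the kidney-gene list
are inputs, not live look-ups.

# Numerical choices and problem sizes

All randomness flows through explicit integer seeds, recorded in the
simulator's output; panels are byte-identical across runs. Tolerances:
credible-set PPs sum to 1 within $10^{-9}$; post-GC $\lambda$ equals 1
within $10^{-6}$; the binomial tail matches direct PMF summation within
$10^{-12}$. Degenerate inputs fail loudly (empty locus, ambiguous
coding, singular meta-regression design, $|\rho| \ge 1$) rather than
returning NA. The validation suite runs at desk scale by design: 100
studies for coding inference, 100 random 12-variant loci against the
selection oracle, 500 replicates for credible-set coverage, 200 each
for shared- and distinct-causal colocalization, 200 random instances
for the locus oracle, and a 10-study, 900-variant, 15,000-per-sex
panel for the end-to-end recovery of planted male-specific,
female-specific and sex-differential loci.

# Known limitations

Summary statistics only: no genotype-level interaction regression, no
imputation modeling, no relatedness. Fixed-effect pooling only (no
random-effects option). The conditional selection is standardized-scale
and will diverge from frequency-aware implementations when per-variant
sample sizes differ wildly within a locus. Ancestry axes are inputs;
deriving them is out of scope. Binary traits are analyzed on the
beta/SE scale without case-control-specific priors.
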