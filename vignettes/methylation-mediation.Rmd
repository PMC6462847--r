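---
title: "Triangulating DNA methylation as a mediator of genetic disease liability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating DNA methylation as a mediator of genetic disease liability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A SNP that is both a methylation quantitative trait locus (mQTL) and a
disease risk variant admits four explanations: **(A) mediation** — the
variant changes methylation, which changes disease liability; **(B)
reverse causation** — overall genetic liability to the disease perturbs
methylation downstream; **(C) linkage** — two distinct causal variants in
LD, one per trait; **(D) horizontal pleiotropy** — one variant, two
independent pathways. Deciding between them from summary statistics is
the core task this package addresses, for binary traits such as
non-syndromic cleft lip/palate where methylation is measured in an
accessible tissue (cord or whole blood) and disease genetics come from
case-control and trio GWAS.

No single analysis separates the four. The package therefore triangulates
three: forward two-sample Mendelian randomization (methylation as
exposure), reverse MR (liability as exposure), and a joint-likelihood
colocalization test, combined by an explicit decision table. Because most
CpGs are instrumented by a single variant, MR alone cannot distinguish A
from D; positive calls are therefore labelled
`putative_mediation_or_pleiotropy`, never plain mediation.

## The models and estimators

**Forward MR.** For instrument $j$ with SNP–methylation effect
$\hat\gamma_j$ (SD of normalized methylation per allele) and SNP–disease
effect $\hat\Gamma_j$ (log odds per allele), the Wald ratio is
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order SE
$\mathrm{se}(\hat\Gamma_j)/|\hat\gamma_j|$ (no exposure-uncertainty term:
standard two-sample practice, valid for strong instruments). Several
independent instruments combine by inverse-variance weighting, which is
algebraically the zero-intercept regression of $\hat\Gamma$ on
$\hat\gamma$ weighted by $1/\mathrm{se}(\hat\Gamma)^2$. Instruments in
residual LD are re-tested by generalized least squares with
$\Omega = S\rho S$, where $S$ is the diagonal of outcome SEs and $\rho$
the *signed* LD correlation matrix (signed $r$, not $r^2$ — the sign
carries the direction of allelic coupling and the estimator is wrong
without it). The GLS solution maximizes the multivariate-normal
likelihood $\hat\Gamma \sim N(\beta\hat\gamma, \Omega)$, which the test
suite verifies against direct numerical maximization; at $\rho = I$ it
reduces exactly to IVW. Fixed-effect (not multiplicative-random-effect)
SEs are used and labelled as such.

**Reverse MR.** Independent genome-wide-significant disease SNPs are the
exposure; their effects on methylation at the focal CpG are the outcome;
IVW combines them. The first-order SE again assumes strong instruments —
the calibration study sizes its disease cohort so instrument z-scores sit
around 6, and documents that the test becomes mildly anticonservative
below that regime. This step is power-limited in practice, so a
non-significant reverse test is weak evidence; the classifier records
that caveat in its notes.

**Colocalization.** Within a window around the disease lead SNP, each
trait's association z-score vector is modelled as
$z \sim N(\lambda R_{\cdot j}, R)$ under a single causal variant at $j$,
with $R$ the signed LD matrix. Profiling $\lambda$ gives a closed-form
maximized likelihood per index; because $R^{-1}R_{\cdot j} = e_j$, the
profiled log-likelihood gain over the null is exactly $z_j^2/2$, which
keeps the permutation loop cheap. The statistic contrasts the best
trait-2 (methylation) likelihood over the *shared support* (SNPs with
$r^2 \ge 0.8$ to the trait-1 lead — the genetic resolution limit) against
the best over the *distinct support* ($r^2 < 0.75$; the 0.05 buffer
below the threshold keeps near-threshold SNPs from being penalized as
"distinct"). Positive values favor one shared variant. Significance
comes from permuting the trait-2 phenotype residuals across individuals
and recomputing the z-scores each time, with the add-one estimator
$p = (1 + \#\{\Lambda_{perm} \ge \Lambda_{obs}\})/(1 + B)$. Windows in
which either support is empty return an explicit sentinel rather than a
number. Design choices left open by the published tooling — max versus
sum over the support, and permuting phenotypes rather than genotypes —
are resolved as: max by default (a likelihood-ratio reading; the summed,
Bayes-like variant is available via `agg = "sum"` for sensitivity), and
phenotype permutation (it needs only the trait-2 cohort and preserves
the genotype LD exactly).

**Decision table** (applied in order): forward MR not significant →
`no_signal`; forward and reverse significant → `reverse_causation`;
colocalization undefined → `indeterminate`; colocalization significant →
`putative_mediation_or_pleiotropy`; otherwise `linkage`. The forward
gate defaults to Bonferroni $\alpha/n_{CpG}$; the reverse and
colocalization gates to nominal 0.05. Putting the reverse gate ahead of
colocalization is a deliberate, conservative formalization of a
precedence the narrative framework leaves open: when both reverse MR and
colocalization are positive, the call goes to reverse causation rather
than mediation.

## Upstream stages

The GWAS side reproduces standard practice: a transmission
disequilibrium test on affected-offspring trios
($\chi^2 = (b-c)^2/(b+c)$ on transmissions $b$ and non-transmissions $c$
from heterozygous parents, with $\log(b/c)$ and $\sqrt{1/b+1/c}$ carried
for meta-analysis, Haldane +0.5 on zero cells), fixed-effects
inverse-variance meta-analysis with allele harmonization (sign flips for
swapped alleles, strand flips by complement, palindromic SNPs dropped
when the effect-allele frequency is in $[0.42, 0.58]$ or missing), and
greedy LD clumping ($r^2 < 0.001$ within 250 kb, ties broken by p then
SNP id so results are order-invariant). Duos are handled as trios with
one parent masked; the observed heterozygous parent contributes only
when the child is homozygous (the transmission is then determined). That
rule is stated rather than inherited: it slightly under-uses duos and
carries a mild allele-frequency bias, so all calibration claims are made
for complete trios.

The mQTL side reproduces the cord-blood database recipe: rank-based
inverse-normal transformation $\Phi^{-1}((r_i - 0.5)/n)$ with average
ranks for ties, residualization on sex, 10 ancestry PCs, batch and cell
proportions (one batch level and one cell column dropped — proportions
are compositional), then per-SNP simple regression of the residuals
within a symmetric, boundary-inclusive 1 Mb cis window, keeping
$p < 10^{-7}$. Residualize-then-regress is kept as a two-stage procedure
(matching the recipe) rather than a joint fit; on simulated data the
difference is negligible because genotype and covariates are
independent. Additively coded dosage is assumed throughout.

## What the generator simulates — and what it does not

`generate_scenario()` builds a single-chromosome study: haplotypes from a
latent-Gaussian threshold model (exchangeable latent correlation per
block, dichotomized at the MAF quantile), a 21-SNP focal block whose
middle SNP is the causal mQTL (latent $\rho = 0.995$, giving typical
within-block genotype $r^2 \approx 0.85$ — above the 0.8 resolution
limit, as in a well-tagged GWAS region), a 5-SNP secondary block 60 kb
away that is LD-coupled to the focal block only under linkage (the
latent cross-correlation is solved numerically from the bivariate-normal
orthant probability so the genotype $r^2$ between the two causal SNPs
hits `linkage_r2` exactly), and six independent background disease SNPs
0.3–0.8 Mb away. Latent methylation is linear in dosage, covariates and
Gaussian noise, then mapped through the logistic function to produce
beta-values in $[0,1]$ — a monotone map, so the inverse-normal transform
in the scan recovers the latent scale exactly. Disease follows a
liability-threshold model: predictor plus standard-normal residual,
thresholded at the $1-K$ quantile of the *total* theoretical liability
distribution, so realized prevalence matches $K$ under every causal
model (a literal unit-variance threshold would inflate prevalence
whenever the predictor is non-null). Trios are ascertained on affected
children by rejection sampling (capped at $10^6$ families).

Default effect sizes are the "strong, detectable locus" regime the
evaluation suite quotes: mQTL effect 0.7 latent SD per allele,
methylation-to-liability 0.7 liability SD per methylation SD, direct
SNP-to-liability 0.7 per allele, liability-to-methylation 0.7, disease
prevalence 0.1, six background SNPs at 0.4 liability units per allele
(instrument strength comparable to genome-wide-significant hits), MAFs
0.2–0.4, and `linkage_r2 = 0.5` — comfortably below the 0.8 resolution
limit, which is what makes linkage distinguishable at all.

The generator deliberately omits: recombination-map realism, imputation
error, X chromosome, population stratification, trans-mQTL, cell-type
deconvolution (estimated proportions are consumed as given covariates),
and any multi-CpG correlation structure. Passing tests therefore show
that the estimators and the classifier behave correctly under the
assumed generative models — not that real cleft data would yield the
same loci.

## Scales, attenuation, and what "recovery" means

Methylation-to-liability effects are generated on the liability (probit)
scale; the forward MR estimate is a log odds ratio per SD methylation,
estimated by logistic regression. No closed-form conversion is asserted.
Instead `eval_forward_recovery()` measures the attenuated truth
empirically: one very large cohort (default $3\times10^5$) gives the
ratio of the logistic SNP–disease coefficient to the linear
SNP–methylation coefficient, and the pipeline's median estimate over 200
two-cohort replicates (methylation n = 1000, disease n = 2000) is
compared with that oracle. At the default settings the measured
liability-to-log-odds factor is about 1.4, and the median pipeline
estimate recovers the attenuated truth within a few percent.

## Numerical choices

LD matrices get a $10^{-6}$ ridge on the diagonal before any inversion;
the profile likelihood uses the same ridge. P-values are two-sided
normal from $\hat\beta/\mathrm{se}$ throughout the summary-statistic
stages, except the TDT, whose record keeps the exact chi-square p it
reports alongside the log-odds beta/SE used for meta-analysis.
Monomorphic SNPs error in LD computation, are dropped with reasons in
association scans, and perfect separation in logistic fits is flagged
(SE sentinel) and excluded. Permutation p-values use the add-one
estimator, bounded below by $1/(B+1)$. All generators are pure functions
of their seeds; two calls with identical configs are bit-identical.

## Problem sizes in the evaluation suite

The self-evaluation battery (`eval_*` functions, also run by
`scripts/acceptance.R`) uses: 1000 null replicates of 100 trios for TDT
calibration; 500 independent null SNPs at n = 1500 for case-control
calibration; 500 two-cohort replicates (n = 800 methylation, n = 2500
disease) for reverse-MR specificity; 500 replicates of n = 150 for the
subtype ANOVA; 500 linkage replicates with 200 permutations each for
colocalization type-I error; 200 replicates for forward recovery; and 50
loci per causal model with 200 permutations for end-to-end
discrimination. These sizes give Monte-Carlo bands tight enough for the
stated checks (binomial 95% band of ±0.019 at 500 replicates) while the
whole battery completes in minutes on one CPU.

## Known limitations

Reverse MR is power-limited by construction (few instruments, modest
variance explained), so `reverse_causation` calls are more trustworthy
than their absence. The duo rule discards ambiguous transmissions.
First-order MR standard errors understate uncertainty when instruments
are weak. The colocalization model assumes a single causal variant per
trait per window; allelic heterogeneity is out of scope, as are Bayesian
posterior-probability colocalization and conditional analysis. And the
mediation-versus-pleiotropy ambiguity is fundamental at single-instrument
loci — the package names its positive calls accordingly.
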