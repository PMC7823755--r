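---
title: "Multibreed genomic evaluation of dairy goat lactation traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multibreed genomic evaluation of dairy goat lactation traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`capragen` implements single-trait genetic evaluation for a mixed-breed
dairy goat herd by two routes and a protocol for comparing them:

* **PBLUP** — best linear unbiased prediction of an animal model using the
  pedigree numerator relationship matrix **A**;
* **ssBC** — a single-step BayesC marker regression that carries
  non-genotyped animals through pedigree-imputed marker covariates.

This vignette is the package's account of the models, the choices that were
genuinely open, and what the synthetic herd generator does and does not
emulate.

## The animal model

For one trait (305-day milk, fat or protein yield, or somatic cell score),

$$\mathbf{y} = \mathbf{Xb} + \mathbf{ZDd} + \mathbf{Za} + \mathbf{e},$$

where **b** holds the parity contemporary group (classes 1–4 and 5+,
reference class 1) and the covariates deviation-from-median-kidding-date
(DMKD, days), days in milk (DIM, days, entered linearly) and general
heterosis; **D** carries each animal's ANTO and unknown breed-group
fractions with the Saanen coefficient constrained to zero; and
$\mathbf{a}\sim N(\mathbf{0},\mathbf{A}\sigma_g^2)$,
$\mathbf{e}\sim N(\mathbf{0},\mathbf{I}\sigma_e^2)$. Breed composition is
computed by averaging parental fractions down the pedigree, an unrecorded
parent contributing a fully "unknown" fraction; general heterosis is
$1-\sum_j d_j^2$ over the three breed-group fractions (0 for a purebred,
exactly 0.5 for an F1). Across-breed values are
$\widehat{EBV} = \mathbf{D\hat d} + \hat{\mathbf{a}}$.

Henderson's mixed model equations are solved dense, and prediction error
variances come from the inverse coefficient matrix — exact at herd sizes of
a few thousand equations, so no approximation is used. Reliability is
$1 - PEV/\sigma_g^2$ with $\sigma_g^2$ the *total* genetic variance, and
accuracy its square root. `A` is built by the tabular method with full
inbreeding; its sparse inverse by Henderson's rules with the
Meuwissen–Luo-style inbreeding adjustment (Mendelian sampling variance
$0.5 - (F_s+F_d)/4$), verified against the dense inverse.

## The single-step BayesC model

Genotyped animals carry centered marker covariates $\mathbf{M}_g$;
non-genotyped animals carry their conditional expectation given genotyped
relatives, $\mathbf{M}_n = \mathbf{A}_{ng}\mathbf{A}_{gg}^{-1}\mathbf{M}_g$
(computed by solving in $\mathbf{A}_{gg}$, never inverting it). The model
adds: breed-specific **J** covariates (the full breed-fraction matrix for
genotyped animals, the same projection for non-genotyped ones) whose
coefficients **q** absorb mean breeding-value differences between
genotyped-founder and non-genotyped-founder animals of each breed group; a
residual polygenic effect $\mathbf{u}\sim N(\mathbf{0},\mathbf{A}w\sigma_g^2)$
for the genetic variance the markers do not capture; and an imputation
residual $\varepsilon$ for non-genotyped animals with variance
$(\mathbf{A}_{nn}-\mathbf{A}_{ng}\mathbf{A}_{gg}^{-1}\mathbf{A}_{gn})(1-w)\sigma_g^2$.
Marker effects follow the BayesC two-component mixture: zero with
probability $\pi$, else $N(0, \sigma^2_{a})$ with a common variance across
loci.

Defaults follow the study design the package reproduces: $\pi = 0.98$,
fixed, never sampled; $w$ defaults to the polygenic share of the
component table per trait (0.88–0.90); chain length 50,000 with 1,000
burn-in; and the per-trait variance components are treated as known
parametric values (milk 9098.6 / 1011.0 / 30,345.0; fat 8.66 / 1.33 /
35.20; protein 5.69 / 0.88 / 23.10; SCS 0.51 / 0.08 / 2.50 for
polygenic / marker / residual variance).

### Sampler

`ssbc_gibbs()` is a single-site Gibbs sampler (C++ core) cycling over:

1. all flat-prior effects (**b**, **d**, **q**) as one multivariate-normal
   block — single-site updates mix far too slowly along the
   intercept/J/breed directions, which are nearly collinear in a herd
   where breed fractions sum to one for every genotyped animal. Exactly
   aliased columns (e.g. the Saanen J covariate when every phenotyped
   animal is genotyped) are pinned to zero, as `lm()` does;
2. each marker's indicator/effect pair from the BayesC full conditional
   with fixed $\pi$;
3. the polygenic effects through the sparse $\mathbf{A}^{-1}$;
4. the imputation residuals through the non-genotyped block of
   $\mathbf{A}^{-1}$ — by the Schur-complement identity this block *is*
   the precision of $\varepsilon$ up to the scalar $(1-w)\sigma_g^2$, so
   the dense conditional covariance is never formed;
5. variances from scaled-inverse-$\chi^2$ full conditionals with
   $\nu = 4$ and prior scales matching the parametric values. By default
   only the common marker variance is sampled
   (`update_marker_variance = TRUE`) — holding it fixed makes moderately
   large QTL undiscoverable because their Bayes factors are computed
   under a far-too-small effect prior — while $\sigma_e^2$ and
   $\sigma_g^2$ stay at their parametric values
   (`update_variances = FALSE`), as the study design prescribes.

All randomness flows through R's RNG, so one seed makes a run
bit-reproducible. Retained draws are exactly
`(n_iter - burn_in)/thin`. Convergence is monitored with the Geweke
diagnostic (`geweke_z()`, autoregressive spectral-density estimator,
first 10% vs last 50% windows) on the residual variance, the genetic
variance and a tracer marker.

### Genomic breeding values, reliability, and two deliberate choices

`ssbc_gbv()` summarizes, per retained draw,

$$\widehat{GBV} = \mathbf{D\hat d} + \mathbf{J\hat q} +
  \mathbf{M}\hat\alpha + \hat\varepsilon + \hat{\mathbf{u}},$$

the point estimate being the posterior mean. Two choices here were
genuinely open and are worth recording:

* **The polygenic effect belongs in the GBV.** With $w \approx 0.9$ the
  residual polygenic effect is ~90% of every animal's genetic merit;
  a "GBV" without it correlates with true breeding value *worse* than the
  pedigree EBV does and carries a mechanically inflated reliability. The
  marker-plus-breed-only definition remains available
  (`include_polygenic = FALSE`).
* **PEV excludes the fixed breed part.** The PEV is the posterior
  variance of the draws of the animal's *genetic deviation*
  ($\mathbf{M}\alpha + \varepsilon + \mathbf{u}$). This is exactly
  parallel to the animal-model PEV, which likewise excludes the variance
  of the fixed-effect solutions: including the **d**/**q** uncertainty
  would charge every animal for the herd-level breed-mean directions,
  which are weakly identified (near-collinear with the intercept) and are
  reported separately with their own standard errors. Reliability and
  accuracy then use the same formulas as PBLUP.

Because **d** and **q** are individually confounded but well identified in
sum, the reporting layer always presents $\hat d_f + \hat q_f$ per breed
group (`combine_breed_and_J()`), with the SE of the per-draw sum.

## Validation protocol

`run_validation()` reproduces the comparison protocol: edit the lactation
records (length < 105 d, milk < 100 kg, fat or protein < 3 kg,
|DMKD| > 90 d removed; boundaries kept — the rules are strict
inequalities); split the herd by age, the oldest 70% (by birth order,
ties by identifier) forming the training set; fit both models on training
phenotypes only; classify validation animals by available pedigree
information (A: both parents recorded; B: sire recorded with ≥ 5 progeny;
C: dam recorded with a lactation record; D: no recorded parents — labels
overlap and are reported independently); rerun both models after masking
the parents of scenario-A animals; standardize EBVs and GBVs to the
training-set mean (the base group is a reporting choice, stated in every
report); and regress standardized GBV on standardized EBV — the slope is
the genomic-inflation measure with expected value one.

Accuracy summaries are means of per-animal accuracies, and percent gain is
computed from unrounded means, then rounded.

## The synthetic herd generator

Real herd-test data of this kind are confidential, so `simulate_herd()`
generates herds with the statistical structure the analysis assumes,
with ground truth for recovery testing:

* **Pedigree**: 46 founder sires with gamma-skewed usage (a few large
  paternal half-sib families, many small), a wide pool of 589 founder
  dams without records, and three cohorts of 280/280/279 recorded does;
  3% of matings use a phenotyped doe as dam. Recorded sires are missing
  for 3% of does and recorded dams for 33% — chosen so the
  scenario-A/C/D composition of a 252-animal validation set matches the
  design the protocol expects (roughly 160/6/1). Missing parents also
  propagate "unknown" breed fractions.
* **Genotypes**: founder allele frequencies by the Balding–Nichols
  construction at Fst 0.1 between Saanen and ANTO around common ancestral
  frequencies; Hardy–Weinberg founders; Mendelian gene dropping of
  unlinked loci; 2,000 markers; 46% of does genotyped, biased toward
  recent cohorts; 0.5% missing calls.
* **Traits**: parity, DMKD (uniform on ±90 d) and DIM (uniform 185–305 d)
  effects — conventions, not data facts —, breed-group means, a heterosis
  effect, 40 QTL among common panel markers with i.i.d. normal effects
  rescaled so the realized marker-linked variance is exactly
  $(1-w)\sigma_g^2$, a polygenic term drawn through the pedigree Cholesky
  of $\mathbf{A}w\sigma_g^2$, and a Gaussian residual. The QTL
  architecture deliberately matches the mixture prior (sparsity comparable
  to $(1-\pi)\,p$), so parameter-recovery tests are well posed; a
  deliberately prior-mismatched variant is available via
  `qtl_large_share`, which concentrates a chosen fraction of the marker
  variance in one locus. Somatic cell score is delivered through eight
  per-test lognormal somatic cell counts per lactation, so the score is
  computed from counts exactly as in real data.

What the generator does **not** emulate: linkage and LD (loci are
unlinked, so markers tag only the planted QTL, not the polygenic
background), selection across generations, genotyping errors, and
repeated lactations. Consequently, passing tests show that the estimators
do what they claim under the assumed generative model; they do not show
that genomic gains of any particular magnitude will materialize in a real
herd, where LD between a dense panel and all causal loci is the dominant
source of genomic information.

## Numerical choices and degenerate inputs

* Pedigrees are sorted by Kahn's algorithm with ties broken by birth
  order then identifier; cycles and duplicate identifiers are hard
  errors; parents appearing only as parents become founders.
* Covariates are centered before solving and the intercept is reported on
  the original scale.
* All-zero design columns are dropped (coefficient zero); non-zero
  confounded columns are a named error in PBLUP and are pinned to zero in
  the sampler.
* PEVs outside $[0, \sigma_g^2]$ (possible through fixed-effect
  uncertainty or Monte-Carlo noise) are clipped with a warning;
  reliabilities are clipped to $[0,1]$.
* The Geweke statistic is defined as 0 for a constant chain (fixed
  variances produce constant variance chains).
* The SNP QC order is animals first (call rate < 0.95), then markers
  (call rate < 0.90, MAF < 0.01, Hardy–Weinberg $p < 10^{-6}$ by a 1-df
  $\chi^2$ without continuity correction, computed on the pooled herd);
  missing dosages are then mean-imputed per marker before centering.

## Problem sizes used by the test suite

The statistical checks in `tests/testthat/` run reduced problem sizes,
chosen as the package's own trade-off between resolution and runtime: the
masking/accuracy contrast uses the default 839-doe herd with its
2,000-marker panel and 10,000-iteration chains over 10 seeds; the
SNP-BLUP equivalence uses 140 animals × 100 markers with 20,000
iterations; the variance-recovery check uses 25 replicates of a 200-doe
herd with 2,500-iteration chains; heritability recovery uses one
2,000-doe herd. A production analysis would use the 50,000-iteration
default.

## Known limitations

* The breed/J confounding means individual **d** and **q** posteriors are
  diffuse and slow-mixing; only their sums are interpretable.
* Fixed $\pi$ with a common marker variance underfits architectures with
  a single very large QTL unless the marker variance is sampled (the
  default) — and even then a locus carrying most of the marker variance
  on an unlinked panel is hard for the mixture to hold in the model.
* PEV-based accuracies inherit Monte-Carlo error from the posterior
  variance estimate; very small true reliabilities can be reported as 0.
* The dense mixed-model solve and PEV inverse are exact but cubic; herds
  beyond ~10,000 pedigree animals would need iterative solvers, which are
  out of scope.
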