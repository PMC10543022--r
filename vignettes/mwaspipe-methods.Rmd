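---
title: "Models and methods behind mwaspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mwaspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the models, their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and
does not emulate, and the numerical choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The quality-control chain

Untargeted mass-spectrometry abundances carry multiplicative technical
structure at three nested levels — run-day, plate, batch — plus pooled
reference samples run repeatedly to measure purely technical variability.
`run_qc_pipeline()` applies, in order:

1. **Run-day median normalisation.** Each value is divided by the median
   of the observed values of its metabolite on its run-day, so every
   (metabolite, run-day) observed median becomes 1. This emulates the
   platform-side correction applied before data delivery; set
   `do_runday_normalize = FALSE` if the input is already corrected.
2. **Sample exclusion.** A sample is dropped when its missing fraction
   exceeds the mean + 5 SD of per-sample missing fractions, computed
   separately within experimental and reference samples so that an
   aberrant reference cannot shift the experimental threshold.
3. **Metabolite exclusion** at > 30% missingness over all samples
   (strictly "over": 30.0% is kept).
4. **Plate masking.** The source procedure is a human judgement ("visible
   measurement issues on a plate"); we formalise it as a rule — a
   (metabolite, plate) cell block is set missing when its plate median
   deviates from the batch median by more than a factor of 4 (either
   direction). The rule is idempotent: a masked plate has no observed
   median and cannot be re-flagged.
5. **Batch median normalisation**, then a **technical CV filter**:
   CV = sample SD / mean (n−1 denominator) over all pooled observed
   reference values of a metabolite; CV > 30% drops the metabolite.
   Pooling over all reference samples is the default; per-batch CVs
   averaged are available behind `per_batch = TRUE` since the pooling
   level is not dictated by the procedure being reproduced.
6. **Wave-missingness test.** Per metabolite, a Fisher exact test on the
   wave × (missing, observed) table over experimental samples; 3×2 tables
   use the exact network algorithm with a seeded Monte-Carlo fallback
   (1e5 draws) when the exact evaluation is infeasible. Metabolites below
   a Bonferroni α (0.05 / metabolites) are imputed within wave rather
   than jointly. Because exact-test p-values are discrete, their null
   distribution is super-uniform, not uniform — the test suite checks
   that the rejection rate never exceeds the nominal level rather than a
   literal Kolmogorov–Smirnov uniformity.
7. **kNN imputation** (k = 10) in metabolite space: profiles are
   standardised per metabolite, distances are Euclidean on
   pairwise-complete entries, and a missing cell receives the mean of the
   k nearest metabolites' standardised values in that sample,
   back-transformed to the target's scale. Sample-space kNN was the main
   alternative; metabolite-space was chosen because biological
   co-regulation makes metabolite profiles the stronger predictor at
   cohort scale, and it is insensitive to cohort composition. Because the
   back-transformed neighbour mean can fall below zero for skewed
   metabolites on the positive abundance scale, imputations are floored
   at the metabolite's smallest observed value — defensible because
   missingness here is predominantly low-abundance-driven. Imputation
   happens on the normalised (pre-log) scale, matching the order of the
   reproduced procedure; observed values are never altered, bitwise.
8. **log2 transform and winsorisation** at mean ± 5 SD per metabolite,
   with mean and SD computed once on the pre-clipping log2 values
   (single pass, not iterated — the clipping bound is a fixed function of
   the original distribution). Winsorisation is monotone: within-
   metabolite value order is preserved.

One subtlety the tests document: even with technical noise switched off
in the generator, the reference CV measured *after* median normalisation
is not exactly zero, because each run-day median is estimated from a
finite number of biologically varying samples. The exact-zero invariant
holds on the raw reference values; after normalisation a floor of a few
percent remains. This also sets how well the estimated CV can rank the
true CV (Spearman ≈ 0.93 at defaults), and motivated the default layout
of 2 run-days per batch (~140 samples per run-day median).

## Family-clustered association models

`fit_clustered_model()` estimates, per metabolite, a marginal Gaussian
model by generalized estimating equations with an exchangeable working
correlation over families and a cluster-robust sandwich covariance. For
the exchangeable structure the working covariance inverse has the closed
form V⁻¹ ∝ I − c·J with c = ρ/(1 + (nᵢ−1)ρ), so the estimating equations
and the sandwich reduce to per-cluster sums that depend on the cluster
only through its size; the implementation exploits this to vectorise over
clusters, which is what makes the 10,000-model calibration experiments in
the test suite affordable. ρ is the usual moment estimator from products
of standardised residual pairs within clusters; iteration stops when the
coefficient change is below 1e-8 (relative), capped at 25 iterations.
With singleton clusters (or the independence working correlation, behind
`corstr = "independence"`) the coefficients coincide with OLS exactly,
which the tests assert to 1e-10. Wald p-values use the normal reference,
standard for GEE at hundreds of clusters.

Modelling conventions:

* Metabolite values (and the IDS severity score, when it is the exposure)
  are z-scored, so betas are in within-metabolite SD units — comparable
  across metabolites, and directly matching the effect sizes the
  generator plants.
* MDD status enters as a 3-level factor with controls as reference;
  smoking as two dummies (ex, current) against never; shipment as a
  factor. Complete-case rows per model, with `n_used` reported.
* The severity model regresses the metabolite on IDS (plus covariates),
  not the reverse; the source's methods and results disagree on the
  direction, and the methods direction is implemented as the default
  (the reverse is a one-line `model_spec` change, and betas from the two
  directions are proportional under z-scoring).
* BH q-values are computed within each contrast family separately
  (current-vs-control, remitted-vs-control, severity), since hit counts
  are reported per contrast.

The antidepressant screen refits the status model without any AD users,
fits class-exposure models (SSRI/TCA/SNRI use vs non-use; classes with
fewer than 10 users are skipped — at the default cohort size this is
typically TCA), and flags any hit whose absolute class beta strictly
exceeds 2× its absolute current-MDD beta. Replication of a candidate at
follow-up requires nominal p < 0.05 for status *or* severity with the
same sign as the baseline current-MDD beta, fitted by plain linear models
(no family structure at follow-up).

## Pathway enrichment

`fisher_enrichment()` tests each super and sub pathway as a 2×2 table of
(hit, non-hit) × (in, out of pathway), restricted to the
pathway-classified universe — unclassified metabolites are removed from
both margins before testing. Two-sided p-values follow the
minimum-likelihood convention (sum of all hypergeometric outcomes no more
likely than the observed one), the convention of standard exact-test
implementations, and the test suite pins them to a full-enumeration
oracle at 1e-12. Raw p-values are the primary output, with BH q-values
within each pathway level alongside.

## Two-sample Mendelian randomization

Instrument selection keeps biallelic SNVs, removes strand-ambiguous
(A/T, C/G) variants up front — so no frequency-based inference is needed
at harmonization — removes MAF < 1%, keeps p < 5.0e-8, and clumps
greedily by ascending p-value within a 10,000 kb window at r² ≥ 0.001
against a user-supplied LD map; without a map, distance-only clumping is
the documented (conservative) fallback. Harmonization aligns the outcome
to the exposure's effect allele, flipping the sign of the outcome beta
for swapped allele pairs and dropping irreconcilable pairs with a logged
reason.

Estimators, all written from the defining formulas:

* **IVW**: β̂ = Σ bₓbᵧ/sᵧ² ⁄ Σ bₓ²/sᵧ², identically the origin-constrained
  weighted least squares of bᵧ on bₓ. The fixed-effect SE is inflated by
  max(1, √(Q/(k−1))) — the multiplicative random-effects convention —
  with both SEs retained in the return value since the procedure being
  reproduced does not state which was used.
* **Weighted median**: the 50% weighted quantile (linear interpolation
  across cumulative weight) of the Wald ratios with normalised bₓ²/sᵧ²
  weights; SE by a seeded parametric bootstrap (1,000 draws) perturbing
  both studies' betas.
* **MR-Egger**: weighted regression with intercept after orienting every
  SNP to bₓ ≥ 0 (the convention that makes a directional pleiotropy mean
  identifiable in the intercept); t-inference with multiplicative
  overdispersion bounded below at 1. With instruments of nearly equal
  strength the intercept and slope are close to collinear and the
  intercept estimate absorbs part of the slope bias — the generator
  therefore draws heterogeneous per-SNP instrument strengths (below),
  and the recovery tests allow the small analytic trade-off term.
* **Cochran's Q** on Wald ratios with first-order weights bₓ²/sᵧ²,
  χ²(k−1) reference.
* **Global outlier test**: observed weighted RSS of outcome betas around
  leave-one-out IVW predictions, with a simulated null that redraws
  *both* the exposure and outcome betas from their standard errors —
  redrawing only the outcome is anticonservative once the causal effect
  is nonzero, because observed residuals then carry θ²·sₓ² of exposure
  measurement error. p-values use add-one smoothing, so they are bounded
  below by 1/(n_sim+1).
* **Single-SNP and leave-one-out** tables for forest plots, and per-SNP
  F = (bₓ/sₓ)² reported against the F > 10 adequacy convention.

`mr_pipeline()` gates metabolites at ≥ 2 independent instruments (listing
failures with reasons), computes BH q-values across metabolites on the
IVW p-values, and returns per-metabolite details. IVW with noisily
measured exposure effects is attenuated by a factor ≈ 1 − 1/F̄ (regression
dilution); at the default instrument strength (F ≈ 50–100) this is a
~1–2% effect, visible in the parameter-recovery tests and accounted for
there explicitly rather than hidden in a loose tolerance.

## The synthetic-data generator

`simulate_cohort()` draws, per subject, a probit liability with a family
random effect (intra-family correlation 0.3 by default) and cuts it at
the configured status proportions (0.29/0.31/0.40 for
control/remitted/current, mirroring a clinically enriched cohort); an
IDS-like severity score with status-dependent mean and variance plus
liability leakage; covariates with realistic marginals; and
antidepressant-class flags concentrated among currently depressed
subjects (~27% SSRI, ~4% TCA, ~11% SNRI among current). Abundances are
log-normal: log2 abundance = metabolite location + SD × (status effect +
covariate loadings + subject deviation), multiplied on the raw scale by
per-(metabolite, run-day) and per-(metabolite, batch) log-normal factors
and mean-1 technical noise with a metabolite-specific CV drawn from
logNormal(log 0.10, 0.6). Reference samples share one fixed plasma
profile and differ only through the technical terms. A subject's
deviation is correlated 0.7 across waves, so true effects persist to
follow-up. Missingness is MNAR-weighted: cell probability ∝
(1−w)·uniform + 2w·(rank of lowness), w = 0.5 by default, preserving the
configured overall rate.

Defaults are desk-scale study conditions, fixed once: 600 subjects in 450
families, 200 metabolites, two waves (80% follow-up), 4 batches × 2
run-days × 4 plates, 60 reference samples, 5% missingness; 20
depression-associated metabolites at ±0.5 SD (remitted subjects get half
the shift), concentrated in two lipid sub-pathways so enrichment has
signal to find; 3 antidepressant-driven metabolites at 2.5 SD driven by
SSRI use alone. Two of these defaults were calibrated by Monte-Carlo
before the test suite was frozen, in the spirit of power analysis: the
run-day layout (so the reference-CV ranking is identifiable past the
median-estimation floor) and the antidepressant effect (a single-class
drug-metabolism-like effect large enough that the flagging rule fires
reliably — its real-world analogue, a drug catabolite shifted only in
users of one class, is expected to be a many-SD effect).

`simulate_sumstats()` builds paired two-sample GWAS summary statistics:
per SNP, a true per-allele exposure effect of heterogeneous strength
(per-SNP variance explained drawn as mean × U(0.3, 1.7) — equal-strength
instruments would leave the Egger intercept unidentified), observed
effects drawn with the analytic SEs 1/√(2·maf(1−maf)·n), outcome effects
θ·bₓ plus a horizontal-pleiotropy term applied in the exposure-raising
orientation (zero, balanced, or directional mean 0.02), and a
binary-trait outcome SE using the effective sample size
4/(1/n_cases + 1/n_controls) with a 0.25 case-fraction variance factor.
Default sample sizes (14,000 exposure; 246,363 cases / 561,190 controls)
and θ = 0.09 (OR ≈ 1.09 per SD) match the scale of the GWAS setting being
emulated. A configurable fraction of SNPs is palindromic, and a fraction
of outcome records stores alleles swapped, to exercise the selection and
harmonization paths.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: correlated metabolite blocks beyond the
planted effects (imputation quality on real co-regulated panels is
checked with a purpose-built correlated fixture instead), LD between
instruments (the emitted LD map is empty; clumping against a real map is
exercised with constructed fixtures), selection effects of clinical
recruitment (status proportions are set, not modelled), genotype-level
data, instrument winner's-curse, and any form of peak
quantification or compound identification upstream of the abundance
matrix.

## Problem sizes and numerical conventions

The calibration experiments in the test suite use 50 replicates × 200
metabolites for the type-I error of the association models, 100
replicates for effect-size recovery at δ = 0.3, and 200–500 replicates
for the MR estimator properties (coverage, intercept recovery, outlier
power) — sizes at which the Monte-Carlo error is well below the margins
being asserted, while the whole suite stays in the minutes range on one
CPU. Ties in weighted quantiles are resolved by linear interpolation;
clumping ties (equal p) keep file order; the BH step-up is the standard
`p.adjust` implementation, pinned to a brute-force all-thresholds oracle;
all RNG consumption is seeded per stage and recorded in the CLI
manifests, so any run is replayable.

## Known limitations

* The plate-masking rule is a formalisation of a visual-review step; its
  factor-of-4 threshold is a convention, not an estimate.
* GEE inference uses the normal reference without small-sample
  corrections; with very few families the sandwich SEs would be
  anticonservative.
* The weighted-median SE is a parametric bootstrap; analytic alternatives
  exist and give slightly different CIs.
* The global outlier test reimplements only the global RSS test of the
  outlier-detection framework it derives from; per-SNP outlier removal
  and distortion testing are out of scope.
* Fisher exact p-values are discrete; calibration statements about them
  are one-sided (super-uniformity), as discussed above.
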