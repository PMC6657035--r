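---
title: "Methods: a recursive random-forest EWAS pipeline with cell-mixture adjustment"
author: "ewasrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a recursive random-forest EWAS pipeline with cell-mixture adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the parameters that matter and their defaults, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology left genuine latitude.

## Scales and preprocessing

Methylation arrives as beta values, proportions of methylated signal in
(0,1). Association models run on M-values, `M = log2(beta / (1 - beta))`,
whose variance is far more stable across the (0,1) range. Betas are clipped
into `[1e-6, 1 - 1e-6]` at construction; that bounds |M| at about 19.9,
keeps the transform strictly monotone, and never touches a value already
inside the band. The round trip beta to M to beta is accurate to 1e-9.

Before stage-2 modelling, each CpG's M-values are screened for strong
outliers with skewness-adjusted boxplot fences. The skewness measure is the
medcouple: the median of the kernel
`h(x_i, x_j) = ((x_j - m) - (m - x_i)) / (x_j - x_i)` over all pairs
straddling the sample median `m`, with the standard sign kernel for values
tied at the median. We evaluate it by the exact O(n^2) enumeration; at the
few-hundred samples per CpG this pipeline operates on, the fast
O(n log n) algorithm buys nothing and the naive form is trivially
verifiable against independent enumeration. The fences are the
Hubert-Vandervieren construction: for medcouple MC >= 0,
`[Q1 - 1.5 exp(-4 MC) IQR, Q3 + 1.5 exp(3 MC) IQR]` (mirrored for
MC < 0), which collapses to Tukey's fences for symmetric samples.
Quartiles use type-7 (linear) interpolation, the most common default,
fixed here for reproducibility.

Three choices were open and are fixed as follows: trimming operates on the
M scale (the same scale the models use); trimmed values become missing
rather than winsorized; and trimming is done across the full analysis
sample, not within case strata. Note trimming is *not* exactly idempotent:
fences are re-estimated after removal, so a second pass can shed a few more
values in columns whose extremes were trimmed (about a third of Gaussian
columns at n = 200 shed one or two more). Columns untouched by the first
pass are provably untouched by the second; the test suite asserts exactly
that.

## Cell-type deconvolution

Blood methylation is a mixture over cell types, and case status shifts the
mixture (eosinophilia in asthmatics), so cell composition is both a
confounder and a biological signal. Proportions are estimated by the
classic reference-based projection: for each sample, minimise
`|| beta_panel - t(P) w ||^2` over the panel CpGs, subject to `w >= 0` and
`sum(w) = 1`, where `P` is the cell-type-by-CpG reference profile matrix.

The solver is Lawson-Hanson non-negative least squares on a system
augmented with a heavily weighted sum-to-one row, followed by exact
renormalisation; tolerance 1e-9. For noiseless mixtures of the reference
profiles this is exact (vertex and 50/50 mixtures are recovered to 1e-6),
and the test suite cross-checks noisy solutions against an exhaustive
active-set enumeration oracle. We impose the sum-to-one *equality* rather
than the `<= 1` convention some deconvolution implementations use, because
downstream models treat the fractions as compositional covariates; that
also means one component (granulocytes, the dominant fraction) must be
dropped whenever the fractions enter a model with an intercept. Panel CpGs
missing from an assay are dropped with a warning; below 80% coverage the
estimation refuses rather than extrapolate.

## Stage 1: recursive random-forest selection

The discovery cohort is split once, stratified by case status (the default
stage-1 fraction 91/370 mirrors the design this pipeline reimplements).
Stage 1 grows a forest on all CpGs with:

* `ntree = 7500` — large, because importance rankings at p in the
  hundreds of thousands are vote averages and need many trees to settle;
* `mtry = max(1, floor(0.10 p))` — 10% of the *current* predictor count;
* balanced sampling — each tree draws `n_minority` samples per class with
  replacement, countering the ~14% case prevalence;
* permutation importance (unscaled mean decrease in OOB accuracy), chosen
  over Gini importance because it is less biased for the correlated
  features methylation data produce (Gini is available via
  `vim_kind = "gini"`).

Each iteration ranks features by importance, keeps the top
`floor(n/2)` (ties broken by original feature order, deterministically),
and repeats; iteration k holds `floor(n_start / 2^(k-1))` features. The
stopping rule operationalises "the case-specific error levelled off" as:
pick the *largest* iteration whose case-class OOB misclassification is
within `level_off_tolerance` (default 0) of the minimum across iterations.
With tolerance 0 this is simply the deepest iteration attaining the
minimum case error — deterministic, and biased toward fewer features,
which is the point of the recursion. One caveat worth knowing: with a
bootstrap balanced at minority-class size, the two classes contribute
different numbers of *unique* samples per tree, so under a class imbalance
the OOB vote shares are not centred at 1/2 and the case-class error sits
above the control error even for pure noise. The recursion only ever
compares case-class error across iterations, so this offset cancels.

Missing M-values are mean-imputed per feature for forest growing only;
association models remain complete-case. Stage-1 forests see features
only — no covariates — matching the all-predictors screening design.

## Stage 2: association, FDR, replication

Each selected CpG is tested by maximum-likelihood logistic regression of
case status on its (trimmed) M-values: a crude model, and a model adjusted
for sex and six of the seven estimated cell fractions (granulocytes
dropped; nRBC retained for cord panels). Odds ratios are per unit M with
Wald 95% intervals — the conventional EWAS reporting choice over
profile-likelihood intervals. Quasi-complete separation is detected via
fitted probabilities pinned within 1e-7 of 0/1 (the `glm` warning alone is
unreliable: its internal check triggers only at machine epsilon) and
flagged `converged = FALSE` rather than dropped.

Crude-model p-values receive Storey q-values: pi0 estimated on the lambda
grid 0.05, ..., 0.95 by a df-3 smoothing spline through
`#(p > lambda) / (m (1 - lambda))`, evaluated at lambda = 0.95 and clamped
to (0, 1]. Below 100 features the smoother is too noisy, so pi0 is fixed
at 1, making the q-values exactly Benjamini-Hochberg — the test suite
asserts that identity. The discovery rule is crude-model q < 0.05, strict
inequality; the adjusted models quantify how much of each association cell
composition explains but do not gate discovery.

Replication compares per-CpG models across cohorts: direction consistency
(sign of the log odds ratio, assessed only where both fits converged) and
replication significance (p < alpha, strict). The follow-up stage
normalises log2 expression by per-sample 75th-percentile shift (the
"percentile shift" convention; log2 first, then shift), correlates
methylation with a target probe by Spearman's rho, and fits the nested
infant-wheeze models: crude; plus infant sex and season of birth
(dummy-coded, winter reference, empty levels dropped with a warning); plus
cord cell fractions.

## The synthetic cohort generator

The generator produces the study conditions every test and the acceptance
run operate under: 370 samples, 13.9% case prevalence, 66.2% female,
seven-cell-type compositions drawn from a Dirichlet (total concentration
50, control means at typical adult blood values), with the eosinophil
component rescaled so the realised case and control group means are
*exactly* 0.045 and 0.021 — the rescaling preserves the simplex by
renormalising the other components. Cord cohorts (`cord7`) use the same
machinery with nRBC as the shifted component.

Each cell type has a mean-beta profile: 40 marker CpGs per type sit near 0
in their own type and near 1 in the others (half in each direction);
non-marker CpGs share one profile across types. Bulk methylation is the
composition-weighted mixture, planted CpGs get a case shift on the M scale
before noising, and observed betas are Beta-distributed around the mixed
mean with concentration `beta_precision`.

Parameter choices that deserve justification:

* `beta_precision = 45`. The Beta concentration is the generator's *only*
  residual-variation knob, so it stands for total biological plus
  technical variation, not array noise alone: it yields per-CpG M-value
  SDs of roughly 0.5–0.9 at intermediate betas, the scale at which
  variable CpGs in real cohorts spread. Pure measurement noise would be an
  order of magnitude tighter; deconvolution checks that target
  measurement-level dispersion use `beta_precision = 500` (beta SD about
  0.02).
* `planted_effect = -1.0` M-units (cases hypomethylated). This is about
  1.5 within-group SDs. A genuinely open calibration: an effect weak
  enough to put crude per-unit-M odds ratios in the 0.1–0.4 band of
  strong reported associations is, at this noise level and a stage-1
  sample of 91, not reliably retained through ten VIM halvings —
  especially since the 40 eosinophil-marker CpGs are themselves
  case-associated through the composition shift and compete in the
  ranking. We prioritised reliable recoverability (discovery recall
  0.9–1.0 across seeds) and accept that planted crude ORs land at the
  strong end (~0.01–0.05 per unit M).
* Expression probe 1 is `rho_p z_M + sqrt(1 - rho_p^2) eps` with
  `rho_p = 2 sin(pi rho_s / 6)`, the Gaussian-copula mapping from the
  target Spearman `rho_s = -0.22`; the realised mean Spearman at n = 82
  over 200 seeds is within 0.05 of the target. Infant wheeze is driven by
  that probe with log odds `log(3.14)` per unit log2 expression at a 25%
  base rate.
* Two seeds: `rng_seed` drives everything sample-level; `structure_seed`
  drives the cohort-invariant biology (CpG roles and type profiles), so
  that cohorts sharing `structure_seed` are independent draws over the
  same loci — the replication-study setting.

What the generator does *not* emulate: probe-type chemistry and batch or
chip effects, genotype-driven methylation QTLs, correlation among
neighbouring CpGs beyond shared cell composition, and any coupling between
planted CpGs and cell fractions (planted loci are composition-neutral by
construction, whereas real top hits were partly eosinophil markers).
Passing tests therefore demonstrate that the machinery recovers the
signals it models, under clean mixture assumptions — not that it would
survive the artefact structure of a real 450k study.

## Error-rate behaviour under the null

A cohort with `planted_effect = 0` but the eosinophil shift left in is
*not* null for the crude discovery rule: its marker CpGs are genuinely
case-associated via cell mixture, and crude discoveries on such cohorts are
correct behaviour (the adjusted models exist precisely to expose them).
The global null additionally sets `eos_mean_case = eos_mean_control`.
Under that global null, the discovery count is 0 in most runs but not
all — by design: BH/Storey at q < 0.05 controls the false discovery rate
at 5%, and with every hypothesis null the chance that a cohort yields at
least one stray discovery *is* that 5%. Across 20 seeded global-null runs
we observe 18–19 zero-discovery cohorts; expecting 19 or more of 20 is a
coin toss even for an exact implementation (probability about 0.74), so a
19/20 bar should be read as an error-rate sanity check, not a hard
guarantee.

## Numerical conventions and degenerate inputs

* Quantiles: type 7 everywhere (fences, percentile-shift anchor).
* Medcouple of a constant sample: 0, flagged degenerate; fences with zero
  IQR collapse to `[Q1, Q3]`, flagged; columns with under 4 observed
  values are skipped by the trimmer, flagged.
* VIM ties in the halving: broken by original feature order, so reruns
  are bit-identical under a fixed seed.
* Deconvolution: singular reference profiles are an error; per-sample
  panel coverage below 80% is an error.
* p-values entering the q-value machinery must lie in (0, 1]; an empty
  vector is an error; pi0 estimates at or below 0 are clamped to 1/m with
  a warning.
* All pipeline randomness flows from explicit integer seeds; outputs
  contain no timestamps, so artifact files rerun byte-identically.

## Problem sizes

The shipped tests exercise the full study scale where it matters — the
acceptance suite runs discovery on 370 samples by 5000 CpGs with
500-tree forests, plus twenty global-null repeats — and reduced scales
(cohorts of 80–200 samples, forests of 100–500 trees) for the per-module
property checks, which keeps the complete suite to a few minutes on one
core while still covering every code path at realistic shapes. The
default `ntree = 7500` matches the original design and is intended for
real analyses.

## Known limitations

* The OOB vote asymmetry under balanced minority-size bootstraps (above)
  means absolute case-class error levels are not comparable across
  prevalences, only across iterations within one run.
* Wald intervals misbehave near separation; such fits are flagged, not
  corrected (no Firth penalisation).
* The q-value smoother's pi0 is variance-prone for feature counts just
  above the 100-feature fallback threshold; with the typical selected-set
  sizes here (tens of CpGs) the BH fallback is what actually runs.
* The linear EWAS loops `lm` per CpG; at array scale a bulk least-squares
  implementation would be the right tool, but the pipeline only ever runs
  it on selected or moderate-size panels.
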