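---
title: "Methods: linking copy-number alterations to the tumor immune microenvironment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking copy-number alterations to the tumor immune microenvironment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotme)
```

## The problem

Aneuploidy — the gain and loss of chromosome arms and focal regions — is
nearly universal in solid tumors and correlates with poor response to
immune-checkpoint blockade. `karyotme` asks the locus-resolved question:
*which* somatic copy-number alterations (SCNAs), at arm, cytoband, or gene
resolution, are associated with a cold or hot tumor immune
microenvironment, and which of them carry prognostic weight under
immunotherapy. Its users are computational biologists with access to
segmented copy-number calls (GISTIC2-style tables or SEG files), bulk
RNA-seq, deconvolution output such as xCell scores, and clinical
follow-up.

## The cytotoxic Immune Score

The per-sample Immune Score (IS) is a rank-sum statistic over seven
cytotoxic-lymphocyte genes: *CD247*, *CD2*, *CD3E*, *GZMH*, *NKG7*,
*PRF1*, *GZMK*. Each gene is ranked across the samples of one cohort
(ascending, ties averaged), the seven ranks are summed per sample, and
the sums are re-ranked to give the final IS. Because only ranks enter,
the IS is invariant to any per-gene strictly increasing transform of
expression — whether the input is TPM, RSEM, or log-scale values is
irrelevant — and IS values are meaningful only *within* a cohort; the
package never compares them across cohorts.

Samples in the bottom 30 % of the IS are classified immune *cold*, the
top 30 % immune *hot*, the rest intermediate. Boundaries use a ceiling
rule on counts (`ceiling(0.30 * n)` samples in each extreme class when
scores are distinct); tie-averaged ranks at a boundary drop the affected
samples into the intermediate class rather than arbitrarily breaking the
tie, and an all-tied cohort is entirely intermediate. Both percentile
widths are parameters (`low_pct`, `high_pct`), and the realized cutoff
ranks are recorded as attributes of the returned table.

## Copy-number calls and the aneuploidy score

Raw log2 copy-number ratios may first be corrected for tumor purity
$\alpha$ and ploidy $\tau$ with the standard mixture formula
$CN_t = (2 \cdot 2^{x} - 2(1-\alpha))/\alpha$, re-expressed as
$\log_2(CN_t/\tau)$, with $CN_t$ floored at 0.01 copies before the log.
The exact arithmetic used by upstream purity callers is not standardized,
so this correction is isolated in `adjust_for_purity_ploidy()` where it
can be swapped.

Discrete calls use strict thresholds: gain iff $\log_2(CN) > 0.2$, loss
iff $\log_2(CN) < -0.2$; a value exactly at a threshold is neutral. The
per-sample aneuploidy score (AS) is the sum of $|\log_2(CN)|$ over all
non-missing features at one resolution level, without rescaling by
feature count; it enters every association model as a covariate for
global chromosomal instability. The AS is computed on the profile it is
given, so when adjustment is used it should precede scoring — the
pipeline does this.

Segment-to-feature mapping (for SEG input) is an overlap-length-weighted
mean of segment values over the feature interval; a weighted mean rather
than a median because segment means are already length-aggregated
quantities. Features covered below a configurable fraction (default 0.5)
are set to missing. Coordinates are stored 0-based half-open; 1-based
inclusive SEG dialects must be declared with a flag, since the two
dialects cannot be distinguished from the file alone and a silent
misread is worse than a mandatory declaration. Missing values propagate;
nothing in the I/O layer imputes.

## The association engine

For each feature the engine fits direction-stratified regressions:

* a **gain model** excludes samples called *loss* at that feature, and a
  **loss model** excludes samples called *gain*, so the two directions of
  copy-number change never confound one another;
* the predictor of interest is the *continuous* log2 copy number (the
  discrete call is used only for exclusion), with the AS as covariate;
* for immune class, a logistic model of the class indicator (cold vs all
  others, or hot vs all others; intermediates count as controls by
  default, with a `drop_intermediate` option since the alternative coding
  is equally defensible);
* for cell-type abundance, a linear model of the deconvolution score,
  rank-transformed to normal scores by default because xCell-style
  enrichment scores are strongly skewed with a point mass at zero (a
  raw-scale option is retained).

Features with fewer than 20 usable samples (configurable), a constant
predictor, or no outcome variation are skipped with machine-readable
reason codes rather than silently dropped. P-values are BH-adjusted
independently within each (tumor type, level, direction, phenotype)
group, so adding tests in one stratum never changes another stratum's q.

The signed landscape reduces the cold and hot models to one number per
(feature, direction): the phenotype with the smaller q wins and the
score is $-\log_{10}(q)$, positive for hot, negative for cold, ties
breaking toward cold. This min-q reduction is one defensible choice
among several; it is localized in `build_signed_landscape()`.

Cell-type associations pass two filters: any association with p > 0.2 is
dropped, and a (feature, cell type) pair whose gain and loss effects
share a sign is dropped entirely — a genuine dosage effect must point in
opposite directions for gains and losses.

Per-patient single-cell proportion comparisons between altered and
unaltered patients use two-sided Welch t-tests; the degenerate case of
two identical constant groups is defined as t = 0, p = 1.

## Gene-level iOG / TiSG calling

Each gene is summarized by three Spearman correlations across samples:
DNA:IS (copy number vs IS), RNA:IS (expression vs IS) and DNA:RNA (copy
number vs its own expression, i.e. dosage coupling). Spearman is used,
consistent with the rank-based IS; Pearson is available behind a flag.
BH adjustment is per parameter across genes (per-parameter rather than
joint, since the three parameters answer different questions).

Calls follow strict sign-and-threshold rules at q < 0.05 for all three
parameters: an **iOG** is a gene in an amplified region with all three
correlations positive; a **TiSG** is a gene in a deleted region with
positive DNA:RNA and negative DNA:IS and RNA:IS. The TiSG rule is
implemented literally; because its IS signs can also be argued the other
way around (a deleted suppressor of immunity could show positive DNA:IS),
`flip_is_sign = TRUE` applies the opposite convention. Region
eligibility is frequency-based — amplified if gained in at least 10 % of
samples, deleted if lost in at least 10 %, the more frequent direction
winning when both — because peak-membership definitions require an
external significance caller.

A known limitation of any correlation-based caller: genes co-located
with a true driver inherit its copy-number profile and therefore its
correlations, so passengers on a driver's arm are called alongside it.
The package's recovery tests therefore assess false calls on arms
carrying no planted driver; distinguishing drivers from same-arm
hitchhikers requires orthogonal evidence (e.g. the random-forest
classifier over additional gene-level features, or functional screens).

`lasso_select_parameters()` reproduces the feature-selection step:
L1-penalized logistic classification on standardized features with the
penalty chosen by seeded cross-validation (the parsimonious
`lambda.1se` by default). `train_tisg_classifier()` is the
random-forest interface: negatives sampled at 5:1 from the non-gold
universe, a stratified 70/30 train/test split, AUROC from pooled
out-of-fold scores of a stratified 5-fold CV and from the held-out
split, everything reproducible from one seed.

## Survival analysis

Survival models use the wider categorical coding Gain (> 0.3) / Loss
(< −0.3) / Neutral with strict inequalities. The genome-wide landscape
fits, per arm, Gain-vs-Neutral (Loss excluded) and Loss-vs-Neutral
(Gain excluded) univariate Cox models with Efron tie handling — the
same exclusion logic as the association engine, applied to survival by
analogy; contrasts with fewer than 10 events are skipped with reasons.
The signed survival score is $-\log_{10}(p)$ carrying the sign of the
log hazard ratio, and BH runs across arms within each direction.

For cohorts with transcriptome but no DNA, the 1q status is inferred
from expression: `select_1q_panel()` ranks candidate 1q genes by
Spearman DNA–RNA concordance in a reference cohort and keeps the top 50
(ties broken lexicographically, so the panel is deterministic);
`score_1q_from_expression()` averages per-gene z-scores of log1p
expression and classifies the top ceiling(n/4) samples — the top
quartile — as 1q-gain. The z/log1p/mean/ceiling details are the
package's own choices; none is forced by the procedure's description.

The multivariate model fits overall survival jointly on binary
covariates: 1q gain, CD8 T-cell fraction high, B-cell fraction high
(both split at the cohort median by default — the customary cutpoint
when none is specified — with a configurable quantile), TMB high at
**>= 10 mut/Mb inclusive** (deliberately inclusive, in contrast to the
strict SCNA thresholds), and PD-L1 positivity. Only complete cases
enter and their count is reported; constant or duplicated covariates
are an error naming the offender.

## The synthetic cohort generator

`simulate_cohort()` draws every data layer from one seed so each
pipeline stage can be validated against planted truth:

* arm log2 CN from a mixture of a neutral state (Gaussian jitter,
  sd 0.05) and an altered state with |log2 CN| uniform on [0.2, 0.8],
  altered with probability 0.4 per arm — the order of recurrent
  arm-level SCNA frequencies in solid tumors; gene values inherit their
  arm plus focal noise;
* arms carrying a planted directional effect are altered predominantly
  (probability 0.9) in that direction, as recurrently gained or lost
  arms are, and arms hosting a planted iOG (TiSG) are biased toward
  gain (loss);
* expression is log-normal with unit dosage coupling to gene copy
  number; the seven signature genes follow a latent immune infiltration
  variable;
* a planted immune effect of size $e$ shifts the latent infiltration of
  altered samples by $e$ standard deviations toward the cold pole. The
  shift is placed on the latent scale — not injected as a Bernoulli
  log-odds — because cold/hot classes are *derived* downstream by
  ranking signature expression, exactly as in real data; for moderate
  effects a 1-SD shift induces a log-odds of roughly 1.6–1.7 on the
  cold class. An alternative construction with logistic latent noise
  would make the planted number an exact log-odds but caps the
  attainable association z-statistic near 3.7 at n = 300 (|log2 CN|
  never exceeds 0.8), too weak for reliable genome-wide detection — and,
  we would argue, biologically backwards: alterations shift infiltration
  continuously, and the dichotomy is an analysis construct;
* planted iOG/TiSG genes get configurable DNA→RNA and RNA→latent
  slopes whose signs reproduce the calling rules;
* cell-type scores are linear in copy number with Gaussian noise,
  floored at zero;
* survival is exponential proportional hazards (Weibull shape is a
  trivial extension; the exponential keeps planted log-HRs exact) with
  censoring from an independent exponential whose rate is set so the
  expected censored fraction equals the configured rate.

What the generator does *not* emulate: genomic segment/LD structure
along arms, GC or length biases, subclonality, covariance between
immune cell types, non-proportional hazards, informative censoring, and
cohort batch effects. Passing recovery tests therefore demonstrates
that the statistical machinery detects what it claims to detect at the
stated sizes — not that real cohorts will show these effect sizes.

## Numerical choices and degenerate inputs

Ties are averaged at both ranking stages of the IS and in all Spearman
correlations. Threshold comparisons are strict everywhere except the
TMB cutpoint (inclusive). Values exactly at a calling threshold are
neutral. Constant vectors yield missing correlations with reason codes;
constant panel genes are dropped with warnings; all-missing samples get
missing aneuploidy scores. TSV output writes numerics with 17
significant digits so read-back is bit-exact, and missing values as
`NA`. Logistic fits under separation report the usual Wald statistics
with warnings suppressed and are additionally guarded by the minimum
sample and outcome-variation checks.

## Problem sizes used in the validation suite

Recovery properties run at the sizes the effects are specified for:
planted immune effects at n = 300 over 8 arms across 20 seeded
replicates; planted hazard ratio 2.0 at n = 500; planted iOG/TiSG genes
at n = 300 with 60 genes over 20 replicates; type-I-error checks pool
300 null models from 20 cohorts of n = 200. The full suite is a few
hundred assertions and runs in well under a minute on one CPU; the
end-to-end pipeline fixture uses a 150-sample cohort.
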