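---
title: "Methods: immunoglobulin-coating analysis of vaginal bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunoglobulin-coating analysis of vaginal bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`igcoat` analyzes two-channel flow-cytometry measurements of IgA/IgG coating
of vaginal bacteria collected longitudinally (three menstrual-cycle
timepoints: T1 during menses, T2 and T3 after), together with unbound
immunoglobulin concentrations, total protein, and 16S-derived
relative-abundance profiles. This vignette documents the models, the tunable
parameters, the synthetic-data design, the numerical choices, and the known
limitations.

## Gating model

Positivity is judged against a paired no-stain control: per channel, the
threshold is the control mean plus `k` control standard deviations
(default `k = 3`; sample SD, denominator `n − 1`). Thresholding is strict —
an event exactly at the threshold is not bound — because "higher than" rules
are conventionally strict and the choice is only visible at measure-zero
ties.

Population structure replaces manual contour gating with a deterministic
procedure:

1. Events below both thresholds form the double-negative (DN) population.
2. An event is *coated* when above at least one channel threshold. The
   alternative reading (above both) is available via
   `detect_populations(coated_rule = "both")`; we default to "any" because a
   three-population model (DN/DP/IgAd) leaves no separate home for
   single-positive events, and the double-positive population is defined
   operationally as the default coated cluster.
3. Coated events are split on `log(IgA) − log(IgG)` by an exact
   one-dimensional two-means: the optimal 2-cluster solution in 1-D is a
   contiguous split of the sorted values, so all `n − 1` cuts are scanned
   and the minimum within-cluster sum of squares taken (ties: leftmost cut).
   This is deterministic and provably optimal, which lets tests compare it
   against exhaustive enumeration of all bipartitions.
4. The split is accepted as {IgAd, DP} only when the higher cluster's median
   IgA/IgG ratio strictly exceeds `r = 3` times the other cluster's;
   otherwise all coated events are one DP population. With the default
   intensity model the log-ratio spread of a single DP population yields a
   spurious split quotient of about `e^{1.35σ} ≈ 2.2`, safely below 3, so
   the rule does not hallucinate IgAd populations.

Per-channel coating statistics are marginal: percent bound counts events
above that channel's threshold regardless of the other channel; MFI is the
median intensity of those bound events on the raw scale; coating
index `= percent bound × MFI`; MFI per bacterium `= MFI / percent bound`,
flagged undefined when nothing is bound. Thresholds come from each sample's
own no-stain control; a pooled-control fallback (with warning) covers
missing controls — whether the original assay pooled controls per run is not
determinable, so per-sample is the default and the fallback is explicit.

## Unbound immunoglobulins

Concentrations below the plate-specific limit of detection are left-censored.
Each censored value is replaced by the mean of `m = 10` independent draws
from a distribution on (0, LOD); the distribution is uniform by default —
the minimal assumption for a value known only to lie below a plate-specific
floor — and pluggable (`impute_below_lod(draw = ...)`). Imputation happens
per record; replicate averaging, if any, is assumed upstream. Normalization
is `(concentration / total protein) × 1000`, i.e. ng per 1 mg protein, and
bound/unbound ratios divide the coating index by the normalized unbound
concentration of the same isotype (undefined at zero unbound).

## Microbiota grouping

Participants are summarized by per-taxon median relative abundance over
their available samples, then clustered agglomeratively with complete
linkage on Euclidean distances and cut at the final merge into two groups;
the group with higher mean *L. crispatus* abundance is labeled LC. The
distance metric and any pre-clustering transform are genuinely open choices
(the original analysis used a spreadsheet tool whose defaults are not
documented): we use Euclidean distance on raw median abundances, with
correlation distance available behind `distance = "correlation"`. All taxa
participate in clustering; any top-*k* truncation is a display concern.

## Association model

Outcomes are log10-transformed; zeros take half the smallest positive
observed value of that outcome (flagged), since percent-bound values of 0
or 100 must survive the transform. The repeated-measures model is marginal
GLS with categorical timepoint and optionally group fixed effects (no
interaction by default — group and characteristics enter individually) and
an *unstructured* 3×3 within-participant covariance (free variance per
timepoint, free correlation per pair), fitted by REML via
`nlme::gls(correlation = corSymm, weights = varIdent)`. On non-convergence
the model falls back to compound symmetry, then to ordinary least squares —
the OLS terminus also handles noise-free degenerate data exactly. Contrast
degrees of freedom follow the containment convention (participants minus
between-subject parameters, e.g. 23 for a 25-participant two-group study)
rather than the observation count; with 75 correlated observations the
latter overstates the information and undercovers the interval, which our
parameter-recovery simulations confirm. The group effect is a single
pre-specified contrast and is reported uncorrected; the three pairwise
timepoint contrasts are Bonferroni-corrected with family size 3.

Supporting tests: uncorrected Pearson chi-square for 2×2 tables (the
corrected statistic does not reproduce the canonical worked example on the
study's printed counts), Spearman correlation with average ranks and an
exact full-permutation p-value for `n ≤ 9` (the classical null tables are
invalid under ties), and the paired t test with explicit degenerate-case
handling.

## Differential abundance

The two-stage screen-then-score procedure: per-taxon Kruskal-Wallis
(tie-corrected H; chi-square approximation, exact label-assignment
enumeration for total `n ≤ 10`) at `α = 0.01`, then bootstrap
linear-discriminant effect sizes on the passers. Features are rescaled from
relative abundances to the conventional [0, 10^6] range; over `n_boot = 30`
stratified subsamples (two thirds of each class, both classes always
present) a two-class Fisher discriminant is computed with the Moore-Penrose
pseudo-inverse of the pooled within-class covariance — robust to the exact
collinearity of compositional data without random jitter, and exactly
symmetric under mirrored features. Each taxon's per-boot score is the
average of its absolute raw class-mean difference and its component of the
discriminant-axis separation; the final effect size is
`log10(1 + mean score)` and a taxon is discriminative at `≥ 2.0`. The
original procedure's subclass (Wilcoxon) stage is deliberately omitted: the
two-class design here has no subclasses. Class processing order follows
first appearance in the data, so swapping the two labels leaves the
bootstrap stream — and hence every score — identical while flipping
enrichment.

With 8-versus-17 classes the noise floor of the LDA score for compositional
features sits well above 2.0, so the Kruskal-Wallis screen at `α = 0.01` is
the operative false-positive control; simulations show about 1% of
pure-noise taxa pass overall. This mirrors the published procedure's
behavior rather than a defect of the reimplementation.

## Synthetic cohort

The generator reproduces the study design as its defaults: 25 participants
× 3 timepoints, 20,000 events per stained sample with an equal-size
no-stain control, 12/25 participants in the LC group, and an IgA-dominant
population planted (at T2/T3 only, never during menses) with probability
7/12 for LC and 1/13 for nonLC participants — the 2×2 structure whose
printed counts give the chi-square worked example. Fluorescence is
bivariate log-normal per population with diagonal log-scale covariance, a
standard heavy-tailed surrogate that keeps population medians analytically
known. Intensity scales are conventional (no instrument magnitudes are
published in the main text): autofluorescence `lognormal(log 100, 0.3)`
both channels, DP at medians (2000, 1500) — IgA/IgG ratio ≈ 1.3 — IgAd at
(8000, 400) — ratio ≈ 20, an order of magnitude past the 3× rule — and a
×1.5 intensity bump on coated populations at T1, emulating the higher
immunoglobulin load during menses. Mixture weights plant the group
directions reported for this system: DN fraction 0.10 (LC) vs 0.35 (nonLC),
so LC participants have a higher percent bound and coating index and a
lower MFI per bacterium, and nonLC a larger double-negative population.

ELISA panels are log-normal per analyte with timepoint shifts (total IgA
and IgG peak at menses; IgA2 and SIgA trend upward toward T3); LODs vary by
96-well plate, assigned round-robin. Censored records withhold the raw
value but the truth is stored separately, so imputation bias is measurable.
Compositions are Dirichlet with a dominant taxon per participant:
*L. crispatus* with weight 100 (mean share ≈ 0.84) for LC participants,
and a mainly *L. iners* / *G. vaginalis* / *Megasphaera* / BVAB1 dominant
with weight 15 (mean share ≈ 0.44) for nonLC — non-*crispatus* communities
are less extremely dominated, which is also what keeps the nonLC
participants mutually closer than they are to the LC block so that
complete-linkage clustering recovers the two-group structure. A moderate
*Dialister* boost (×5) in nonLC participants plants a marker of the
non-dominated community for the differential-abundance stage.

What the generator does **not** emulate: instrument spillover and
compensation, doublets and debris, day-to-day machine drift, plate effects
beyond the LOD, phylogenetic correlation between taxa, and temporal
autocorrelation of community composition beyond the fixed per-participant
dominant. Passing tests therefore demonstrate the correctness and
calibration of the pipeline's logic under a faithful but idealized data
model — not robustness to every artifact of real cytometry or sequencing.

## Problem sizes and numerical choices

Single-sample validations (planted-fraction recovery, the ratio-rule
boundary) run at the full 20,000 events, where multinomial noise per
fraction is below 0.01. Replicate studies use deliberately lighter sizes
chosen so that the Monte-Carlo error is still far below the effects being
checked: sign-recovery runs 100 cohorts at 2,000 events per sample (gating
noise ≈ 0.01 against planted group differences ≈ 0.25 on the fraction
scale), parameter recovery uses 200 replicates of directly simulated
outcomes, and the differential-abundance rates use 100 runs each of planted
and pure-noise profiles. Determinism: every stochastic function takes a
seed and restores the caller's RNG state; the pipeline and the acceptance
script derive all sub-seeds from one integer.

Degenerate inputs are handled explicitly rather than by failure: empty or
zero-variance controls, samples with no coated events, zero percent bound
(undefined MFI per bacterium), constant features (Kruskal-Wallis p = 1),
constant vectors in correlation (undefined flag), zero-variance paired
differences, zero unbound concentrations, and all-zero abundance columns.
Exact ties at the dominant-taxon argmax break lexicographically and are
flagged.

## Known limitations

- The study's real effect estimates are not reproducible — the underlying
  data are not deposited — so calibration is established on synthetic
  cohorts with planted effects of the reported signs, not by numeric
  replication.
- The population model caps at three populations; a sample with two genuine
  DP populations is summarized as one.
- Satterthwaite degrees of freedom are approximated by the containment
  convention; for the balanced designs targeted here the two agree closely.
- The exact-permutation Spearman p enumerates `n!` permutations and is
  limited to `n ≤ 9`.
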