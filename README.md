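# igcoat

Immunoglobulin coating of vaginal bacteria: flow-cytometry gating, coating
statistics, unbound-immunoglobulin quantification, microbiota clustering and
association analysis.

## The problem

Secretory antibodies in the female genital tract bind commensal and pathogenic
bacteria, and both the amount of coating and the bacterial populations carrying
it change over the menstrual cycle and with the composition of the vaginal
microbiota. A longitudinal study of this system typically collects, per
participant and timepoint: a two-channel flow-cytometry measurement of bacteria
stained for bound IgA (AF647) and IgG (AF488) with a paired no-stain control;
ELISA concentrations of unbound IgA, IgA1, IgA2, secretory IgA and IgG with
plate-specific detection limits; a total-protein measurement of the vaginal
fluid; and a 16S-derived relative-abundance profile. `igcoat` implements the
complete downstream analysis of such a design for R users — from event tables
to the final association statistics — plus a seeded synthetic-cohort generator
with planted ground truth, so every stage can be validated end to end.

## The statistics at its core

* **Gating against no-stain controls.** Per channel *c*, the positivity
  threshold is `mean_c + k * sd_c` of the control events (default `k = 3`). An
  event is bound on a channel when strictly above that channel's threshold.
* **Population detection.** Events below both thresholds form the
  double-negative population (DN). Coated events are split by an exact 1-D
  two-means on `log(IgA) − log(IgG)`; the split is kept as an IgA-dominant
  (IgAd) plus double-positive (DP) pair only when the higher cluster's median
  IgA/IgG ratio exceeds `r = 3` times the other's, otherwise all coated events
  are one DP population.
* **Coating statistics.** Per channel: percent bound `p`, median fluorescence
  intensity of bound events `MFI`, coating index `CI = p × MFI`, and MFI per
  bacterium `MFI / p`.
* **Unbound immunoglobulins.** Below-LOD values are imputed as the mean of 10
  uniform draws on (0, LOD), then normalized to `(conc / protein) × 1000`
  (ng per 1 mg protein). Bound/unbound ratio = `CI / normalized`.
* **Microbiota grouping.** Complete-linkage hierarchical clustering of
  per-participant median abundance profiles (Euclidean distance), cut into two
  groups; the cluster with higher mean *L. crispatus* abundance is the
  LC group.
* **Association.** Outcomes are log10-transformed and fitted with a
  repeated-measures model (unstructured 3×3 within-participant covariance,
  REML), giving the LC − nonLC mean difference with 95% CI and
  Bonferroni-corrected pairwise timepoint contrasts; plus Spearman correlation
  (exact permutation p for n ≤ 9), uncorrected Pearson chi-square for 2×2
  tables, and the paired t test.
* **Differential abundance.** Per-taxon Kruskal-Wallis screen at `α = 0.01`
  followed by bootstrap linear-discriminant effect-size scoring; a taxon is
  discriminative when its log10 LDA score reaches 2.0.

## Worked example

```r
library(igcoat)

coh <- simulate_cohort(cohort_config(events_per_sample = 2000), seed = 2)
rep <- run_pipeline(coh, seed = 2)
rep$igad_table
#>          group
#> igad      LC nonLC
#>   present  7     1
#>   absent   5    12
rep$igad_chisq$p
#> [1] 0.006690927
rep$association$ci_iga[1, c("contrast", "estimate", "ci_low", "ci_high")]
#>            contrast  estimate ci_low  ci_high
#> 1 group: LC - nonLC 0.1458655 0.1407 0.151031
```

Seed 2 plants the same 2×2 structure the study design describes — 8
participants with an IgA-dominant population appearing after menses, 7 of them
in the *L. crispatus*-dominated group of 12 — and the recomputed uncorrected
chi-square p-value is 0.0067 (printed as 0.007). The association row says the
LC group's IgA coating index is higher by 0.14 log10 units (the planted
difference implied by the generator's default mixture weights), with a 95% CI
excluding zero.

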