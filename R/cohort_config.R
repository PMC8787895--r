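#' Default fluorescence population parameters
#'
#' Per-group mixture weights and bivariate log-normal intensity parameters for
#' the three bacterial populations seen in IgA/IgG coating cytometry:
#' double-negative (DN, autofluorescence level), double-positive (DP, coated
#' on both channels) and IgA-dominant (IgAd, high IgA/IgG ratio). The
#' *L. crispatus*-dominated (LC) group carries a smaller DN fraction (fewer
#' uncoated bacteria) than the nonLC group; when a participant exhibits an
#' IgAd population it takes part of the DP mass. Intensities are conventional
#' arbitrary fluorescence units: instrument scales are not part of the study
#' design, only the ordering and ratio structure matter (DP IgA/IgG ratio
#' about 1.3, IgAd ratio about 20, i.e. well past the 3x rule).
#'
#' @param t1_mfi_multiplier multiplicative bump applied to coated-population
#'   intensities at timepoint T1, emulating the higher immunoglobulin load
#'   during menses. Default 1.5.
#' @return nested list with elements `LC` and `nonLC`, each holding `weights`,
#'   `weights_igad` and per-population `meanlog`/`sdlog`, plus the shared
#'   `t1_mfi_multiplier`.
#' @export
default_population_params <- function(t1_mfi_multiplier = 1.5) {
  pops <- list(
    DN   = list(meanlog = c(iga = log(100),  igg = log(100)),  sdlog = c(iga = 0.3, igg = 0.3)),
    DP   = list(meanlog = c(iga = log(2000), igg = log(1500)), sdlog = c(iga = 0.4, igg = 0.4)),
    IgAd = list(meanlog = c(iga = log(8000), igg = log(400)),  sdlog = c(iga = 0.4, igg = 0.4))
  )
  list(
    LC    = c(list(weights = c(DN = 0.10, DP = 0.90, IgAd = 0),
                   weights_igad = c(DN = 0.10, DP = 0.70, IgAd = 0.20)), pops),
    nonLC = c(list(weights = c(DN = 0.35, DP = 0.65, IgAd = 0),
                   weights_igad = c(DN = 0.35, DP = 0.45, IgAd = 0.20)), pops),
    t1_mfi_multiplier = t1_mfi_multiplier
  )
}

#' Default ELISA panel parameters
#'
#' Log-normal concentration models (ng/ml) for the five unbound analytes with
#' timepoint shifts on the log scale (T2 is the reference): total IgA and IgG
#' peak at menses (T1), IgA1 rises at T1, IgA2 and SIgA trend upward toward
#' T3. Limits of detection vary per 96-well plate around an analyte base LOD;
#' plates are assigned round-robin across samples.
#'
#' @return list with `analytes`, `meanlog`, `sdlog`, `tp_shift` (analyte x
#'   timepoint matrix of log shifts), `base_lod` (ng/ml) and `plate_factors`.
#' @export
default_elisa_params <- function() {
  analytes <- c("IgA", "IgA1", "IgA2", "SIgA", "IgG")
  tp_shift <- rbind(
    IgA  = c(T1 = log(2.5),   T2 = 0, T3 = 0),
    IgA1 = c(T1 = log(1.6),   T2 = 0, T3 = 0),
    IgA2 = c(T1 = -log(1.6),  T2 = 0, T3 = log(1.2)),
    SIgA = c(T1 = 0,          T2 = 0, T3 = log(1.3)),
    IgG  = c(T1 = log(3),     T2 = 0, T3 = 0)
  )
  list(
    analytes = analytes,
    meanlog = c(IgA = log(3000), IgA1 = log(1500), IgA2 = log(800),
                SIgA = log(1200), IgG = log(2500)),
    sdlog = c(IgA = 0.6, IgA1 = 0.6, IgA2 = 0.6, SIgA = 0.6, IgG = 0.6),
    tp_shift = tp_shift,
    base_lod = c(IgA = 200, IgA1 = 300, IgA2 = 400, SIgA = 300, IgG = 200),
    plate_factors = c(0.8, 1.0, 1.2, 1.0)
  )
}

default_taxa_names <- function(n_taxa) {
  nm <- c("L_crispatus", "L_iners", "L_jensenii", "L_gasseri", "G_vaginalis",
          "Megasphaera_spp", "BVAB1", "Dialister_spp", "A_vaginae",
          "Prevotella_spp", "Sneathia_spp", "Mobiluncus_spp", "Ureaplasma_spp",
          "M_hominis", "Streptococcus_spp", "Staphylococcus_spp",
          "Bifidobacterium_spp", "F_magna", "Peptostreptococcus_spp",
          "Anaerococcus_spp")
  if (n_taxa <= length(nm)) nm[seq_len(n_taxa)]
  else c(nm, sprintf("taxon_%02d", seq_len(n_taxa - length(nm))))
}

#' Synthetic cohort configuration
#'
#' Builds and validates the configuration of the synthetic longitudinal study:
#' 25 participants sampled at three menstrual-cycle timepoints (T1 = menses,
#' T2, T3), roughly 20,000 cytometry events per sample with a paired no-stain
#' control, an ELISA panel with left-censoring at per-plate limits of
#' detection, total-protein concentrations, and Dirichlet taxon compositions
#' with one dominant taxon per participant. Twelve of 25 participants form
#' the *L. crispatus*-dominated (LC) group; an IgA-dominant population is
#' planted at T2/T3 with probability 7/12 for LC and 1/13 for nonLC
#' participants, reproducing the study's 2x2 association structure.
#'
#' @param n_participants number of participants (default 25).
#' @param timepoints ordered timepoint labels (default `c("T1","T2","T3")`).
#' @param events_per_sample cytometry events recorded per sample (default 20000).
#' @param frac_lc_group proportion of participants in the LC group (default 12/25).
#' @param population_params see [default_population_params()].
#' @param igad_prevalence named probabilities `c(LC=, nonLC=)` that a
#'   participant exhibits an IgA-dominant population at T2/T3.
#' @param control_autofluorescence log-normal location/scale per channel for
#'   no-stain control events.
#' @param elisa_params see [default_elisa_params()].
#' @param protein_params log-normal parameters for total protein (mg/ml).
#' @param n_taxa number of taxa in abundance tables (default 20).
#' @param dirichlet_concentration baseline Dirichlet concentration per taxon.
#' @param dominance_weight multiplier on the dominant taxon's Dirichlet
#'   parameter for LC participants (default 100, giving a mean *L. crispatus*
#'   share of ~0.84 at 20 taxa — the near-complete dominance typical of
#'   *L. crispatus* communities).
#' @param dominance_weight_nonlc multiplier for nonLC participants (default
#'   15, a mean dominant share of ~0.44): non-*L. crispatus* communities are
#'   less extremely dominated, which keeps the nonLC group mutually closer
#'   than it is to the LC group, as the study's two-cluster structure
#'   requires.
#' @param dialister_weight multiplier on the `Dialister_spp` parameter for
#'   nonLC participants, planting a marker of the non-dominated community.
#' @param seed integer seed recorded in the config and used by
#'   [simulate_cohort()] when no explicit seed is given.
#' @return an object of class `cohort_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_participants = 4, events_per_sample = 500)
#' cfg$timepoints
#' @export
cohort_config <- function(n_participants = 25,
                          timepoints = c("T1", "T2", "T3"),
                          events_per_sample = 20000,
                          frac_lc_group = 12 / 25,
                          population_params = default_population_params(),
                          igad_prevalence = c(LC = 7 / 12, nonLC = 1 / 13),
                          control_autofluorescence = list(
                            meanlog = c(iga = log(100), igg = log(100)),
                            sdlog = c(iga = 0.3, igg = 0.3)),
                          elisa_params = default_elisa_params(),
                          protein_params = list(meanlog = log(2), sdlog = 0.5),
                          n_taxa = 20,
                          dirichlet_concentration = 1,
                          dominance_weight = 100,
                          dominance_weight_nonlc = 15,
                          dialister_weight = 5,
                          seed = NULL) {
  cfg <- list(n_participants = n_participants, timepoints = timepoints,
              events_per_sample = events_per_sample,
              frac_lc_group = frac_lc_group,
              population_params = population_params,
              igad_prevalence = igad_prevalence,
              control_autofluorescence = control_autofluorescence,
              elisa_params = elisa_params, protein_params = protein_params,
              n_taxa = n_taxa,
              dirichlet_concentration = dirichlet_concentration,
              dominance_weight = dominance_weight,
              dominance_weight_nonlc = dominance_weight_nonlc,
              dialister_weight = dialister_weight,
              taxa_names = default_taxa_names(n_taxa),
              seed = seed)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  chk_count <- function(x, field, min = 1) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x))
      stop_config(field, sprintf("must be a single integer >= %d", min))
  }
  chk_prob <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1))
      stop_config(field, "probabilities must lie in [0, 1]")
  }
  chk_pos <- function(x, field) {
    if (!is.numeric(x) || any(is.na(x)) || any(x <= 0))
      stop_config(field, "scale parameters must be > 0")
  }
  chk_count(cfg$n_participants, "n_participants", min = 2)
  chk_count(cfg$events_per_sample, "events_per_sample", min = 1)
  chk_count(cfg$n_taxa, "n_taxa", min = 2)
  if (length(cfg$timepoints) < 1 || anyDuplicated(cfg$timepoints))
    stop_config("timepoints", "must be distinct labels")
  chk_prob(cfg$frac_lc_group, "frac_lc_group")
  chk_prob(cfg$igad_prevalence, "igad_prevalence")
  for (grp in c("LC", "nonLC")) {
    gp <- cfg$population_params[[grp]]
    if (is.null(gp)) stop_config("population_params", paste("missing group", grp))
    for (w in c("weights", "weights_igad")) {
      chk_prob(gp[[w]], paste0("population_params$", grp, "$", w))
      if (abs(sum(gp[[w]]) - 1) > 1e-9)
        stop_config(paste0("population_params$", grp, "$", w),
                    "mixture weights must sum to 1")
    }
    for (pop in c("DN", "DP", "IgAd")) chk_pos(gp[[pop]]$sdlog,
      paste0("population_params$", grp, "$", pop, "$sdlog"))
  }
  chk_pos(cfg$control_autofluorescence$sdlog, "control_autofluorescence$sdlog")
  chk_pos(cfg$protein_params$sdlog, "protein_params$sdlog")
  chk_pos(cfg$dirichlet_concentration, "dirichlet_concentration")
  chk_pos(cfg$dominance_weight, "dominance_weight")
  chk_pos(cfg$dominance_weight_nonlc %||% cfg$dominance_weight,
          "dominance_weight_nonlc")
  chk_pos(cfg$elisa_params$sdlog, "elisa_params$sdlog")
  if (any(cfg$elisa_params$base_lod < 0))
    stop_config("elisa_params$base_lod", "LODs must be >= 0")
  cfg
}
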