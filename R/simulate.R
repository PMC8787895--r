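#' Simulate flow-cytometry events for one sample
#'
#' Draws a stained event table from the participant's three-population
#' mixture (DN / DP / IgAd, each bivariate log-normal with diagonal
#' covariance on the log scale) and a paired no-stain control table from the
#' autofluorescence model. The IgA-dominant population is only active for
#' participants carrying the planted IgAd flag, and only at timepoints after
#' menses (never T1). Coated-population intensities at T1 are multiplied by
#' the configured menses factor.
#'
#' @param cfg a [cohort_config()].
#' @param participant_id participant label, e.g. `"P01"`.
#' @param timepoint one of `cfg$timepoints`.
#' @param group `"LC"` or `"nonLC"`; selects the mixture weights.
#' @param igad logical; whether this participant carries an IgA-dominant
#'   population at post-menses timepoints.
#' @param seed optional integer; identical seeds reproduce identical tables.
#' @return list with `stained` and `no_stain` event data frames (columns
#'   `sample_id`, `event_id`, `iga_intensity`, `igg_intensity`) and `truth`,
#'   the planted mixture weights, realized fractions and population medians.
#' @examples
#' cfg <- cohort_config(events_per_sample = 200)
#' ev <- simulate_events(cfg, "P01", "T2", group = "LC", igad = TRUE, seed = 1)
#' head(ev$stained)
#' @export
simulate_events <- function(cfg, participant_id, timepoint,
                            group = c("LC", "nonLC"), igad = FALSE,
                            seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  group <- match.arg(group)
  if (!timepoint %in% cfg$timepoints)
    stop_config("timepoints", paste("unknown timepoint", timepoint))
  gp <- cfg$population_params[[group]]
  igad_active <- isTRUE(igad) && timepoint != cfg$timepoints[1]
  w <- if (igad_active) gp$weights_igad else gp$weights
  t1_mult <- if (timepoint == cfg$timepoints[1])
    cfg$population_params$t1_mfi_multiplier else 1
  n <- cfg$events_per_sample
  sample_id <- paste0(participant_id, "_", timepoint)

  with_seed(seed, {
    comp <- sample(names(w), n, replace = TRUE, prob = w)
    iga <- igg <- numeric(n)
    medians <- data.frame(population = names(w), median_iga = NA_real_,
                          median_igg = NA_real_, row.names = NULL)
    for (i in seq_along(w)) {
      pop <- names(w)[i]
      p <- gp[[pop]]
      mult <- if (pop == "DN") 1 else t1_mult   # menses bump on coated pops only
      idx <- comp == pop
      medians$median_iga[i] <- exp(p$meanlog[["iga"]]) * mult
      medians$median_igg[i] <- exp(p$meanlog[["igg"]]) * mult
      if (any(idx)) {
        iga[idx] <- rlnorm(sum(idx), p$meanlog[["iga"]] + log(mult), p$sdlog[["iga"]])
        igg[idx] <- rlnorm(sum(idx), p$meanlog[["igg"]] + log(mult), p$sdlog[["igg"]])
      }
    }
    af <- cfg$control_autofluorescence
    ns_iga <- rlnorm(n, af$meanlog[["iga"]], af$sdlog[["iga"]])
    ns_igg <- rlnorm(n, af$meanlog[["igg"]], af$sdlog[["igg"]])

    realized <- as.numeric(table(factor(comp, levels = names(w)))) / n
    list(
      stained = data.frame(sample_id = sample_id, event_id = seq_len(n),
                           iga_intensity = iga, igg_intensity = igg),
      no_stain = data.frame(sample_id = sample_id, event_id = seq_len(n),
                            iga_intensity = ns_iga, igg_intensity = ns_igg),
      truth = list(sample_id = sample_id, participant_id = participant_id,
                   timepoint = timepoint, group = group,
                   igad_active = igad_active,
                   weights = w, realized_frac = setNames(realized, names(w)),
                   pop_medians = medians)
    )
  })
}

#' Simulate an ELISA panel for one sample
#'
#' Draws unbound immunoglobulin concentrations (IgA, IgA1, IgA2, SIgA, IgG;
#' ng/ml) from per-analyte log-normal models with timepoint shifts, plus a
#' total-protein concentration (mg/ml). Values below the plate's limit of
#' detection are flagged censored and their raw value is withheld from the
#' record (the truth is returned separately so imputation bias can be
#' measured).
#'
#' @inheritParams simulate_events
#' @param plate 96-well plate index; selects the plate LOD factor
#'   (round-robin over `cfg$elisa_params$plate_factors`).
#' @return list with `records` (columns `sample_id`, `analyte`, `value`,
#'   `lod`, `censored`, `protein_mg_ml`; `value` is `NA` where censored) and
#'   `truth` (uncensored concentrations).
#' @export
simulate_elisa <- function(cfg, participant_id, timepoint, plate = 1L,
                           seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!timepoint %in% cfg$timepoints)
    stop_config("timepoints", paste("unknown timepoint", timepoint))
  ep <- cfg$elisa_params
  sample_id <- paste0(participant_id, "_", timepoint)
  pf <- ep$plate_factors[((plate - 1L) %% length(ep$plate_factors)) + 1L]

  with_seed(seed, {
    protein <- rlnorm(1, cfg$protein_params$meanlog, cfg$protein_params$sdlog)
    shift <- if (timepoint %in% colnames(ep$tp_shift))
      ep$tp_shift[ep$analytes, timepoint] else 0
    conc <- rlnorm(length(ep$analytes), ep$meanlog[ep$analytes] + shift,
                   ep$sdlog[ep$analytes])
    lod <- ep$base_lod[ep$analytes] * pf
    censored <- conc < lod
    list(
      records = data.frame(sample_id = sample_id, analyte = ep$analytes,
                           value = ifelse(censored, NA_real_, conc),
                           lod = unname(lod), censored = censored,
                           protein_mg_ml = protein, row.names = NULL),
      truth = data.frame(sample_id = sample_id, analyte = ep$analytes,
                         true_conc = conc, row.names = NULL)
    )
  })
}

# Dirichlet draw via normalized gamma variates.
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Simulate a relative-abundance column for one sample
#'
#' Draws a Dirichlet composition over `cfg$n_taxa` taxa in which the
#' participant's dominant taxon has its concentration parameter multiplied by
#' `cfg$dominance_weight`. For nonLC participants a `Dialister_spp`-type
#' taxon receives an additional moderate boost, planting a marker of the
#' non-*L. crispatus* community for the differential-abundance stage.
#'
#' @inheritParams simulate_events
#' @param dominant_taxon name of the taxon with the largest expected share.
#' @return named numeric vector of relative abundances summing to 1.
#' @export
simulate_abundances <- function(cfg, participant_id, timepoint,
                                dominant_taxon = cfg$taxa_names[1],
                                group = c("LC", "nonLC"), seed = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  group <- match.arg(group)
  if (!dominant_taxon %in% cfg$taxa_names)
    stop_config("taxa_names", paste("unknown dominant taxon", dominant_taxon))
  alpha <- setNames(rep(cfg$dirichlet_concentration, cfg$n_taxa), cfg$taxa_names)
  dw <- if (group == "LC") cfg$dominance_weight
        else cfg$dominance_weight_nonlc %||% cfg$dominance_weight
  alpha[dominant_taxon] <- alpha[dominant_taxon] * dw
  if (group == "nonLC" && "Dialister_spp" %in% names(alpha))
    alpha["Dialister_spp"] <- alpha["Dialister_spp"] * cfg$dialister_weight
  with_seed(seed, setNames(rdirichlet1(alpha), cfg$taxa_names))
}

#' Simulate a complete synthetic cohort
#'
#' Generates the full study: participant group labels (LC vs nonLC), planted
#' IgA-dominant flags, per-sample stained and no-stain event tables, ELISA
#' panels with per-plate LODs, total protein, abundance compositions and
#' sample metadata, together with a ground-truth record for every planted
#' quantity. All randomness flows from `seed`; the same seed reproduces the
#' cohort bit-for-bit.
#'
#' @param cfg a [cohort_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return object of class `ig_cohort`: a list with `events`, `controls`,
#'   `elisa`, `abundance` (taxa x samples matrix), `metadata`, `truth`
#'   (participants, samples, elisa, dominant tables) and `config`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 4,
#'                                      events_per_sample = 300), seed = 7)
#' table(coh$truth$participants$group)
#' @export
simulate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  nonlc_dominants <- intersect(
    c("L_iners", "L_jensenii", "G_vaginalis", "Megasphaera_spp", "BVAB1"),
    cfg$taxa_names)
  if (!length(nonlc_dominants)) nonlc_dominants <- cfg$taxa_names[2]

  with_seed(seed, {
    n <- cfg$n_participants
    ids <- sprintf("P%02d", seq_len(n))
    n_lc <- round(cfg$frac_lc_group * n)
    group <- rep("nonLC", n)
    group[sample.int(n, n_lc)] <- "LC"
    igad <- rbinom(n, 1, cfg$igad_prevalence[group]) == 1
    dominant <- ifelse(group == "LC", cfg$taxa_names[1],
                       sample(nonlc_dominants, n, replace = TRUE))
    participants <- data.frame(participant_id = ids, group = group,
                               igad = igad, dominant_taxon = dominant)

    grid <- expand.grid(participant_id = ids, timepoint = cfg$timepoints,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[order(grid$participant_id, match(grid$timepoint, cfg$timepoints)), ]
    rownames(grid) <- NULL

    events <- controls <- vector("list", nrow(grid))
    elisa <- elisa_truth <- vector("list", nrow(grid))
    ab <- matrix(NA_real_, cfg$n_taxa, nrow(grid),
                 dimnames = list(cfg$taxa_names, NULL))
    samp_truth <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      pid <- grid$participant_id[i]; tp <- grid$timepoint[i]
      j <- match(pid, ids)
      ev <- simulate_events(cfg, pid, tp, group = group[j], igad = igad[j])
      el <- simulate_elisa(cfg, pid, tp, plate = i)
      ab[, i] <- simulate_abundances(cfg, pid, tp, dominant_taxon = dominant[j],
                                     group = group[j])
      events[[i]] <- ev$stained; controls[[i]] <- ev$no_stain
      elisa[[i]] <- el$records; elisa_truth[[i]] <- el$truth
      tr <- ev$truth
      samp_truth[[i]] <- data.frame(
        sample_id = tr$sample_id, participant_id = pid, timepoint = tp,
        group = group[j], igad_active = tr$igad_active,
        frac_dn = tr$weights[["DN"]], frac_dp = tr$weights[["DP"]],
        frac_igad = tr$weights[["IgAd"]],
        realized_dn = tr$realized_frac[["DN"]],
        realized_dp = tr$realized_frac[["DP"]],
        realized_igad = tr$realized_frac[["IgAd"]],
        dominant_taxon = dominant[j])
    }
    sample_ids <- paste0(grid$participant_id, "_", grid$timepoint)
    colnames(ab) <- sample_ids
    metadata <- rbind(
      data.frame(sample_id = sample_ids, participant_id = grid$participant_id,
                 timepoint = grid$timepoint, stain = "stained"),
      data.frame(sample_id = sample_ids, participant_id = grid$participant_id,
                 timepoint = grid$timepoint, stain = "no_stain"))

    structure(list(
      events = do.call(rbind, events),
      controls = do.call(rbind, controls),
      elisa = do.call(rbind, elisa),
      abundance = ab,
      metadata = metadata,
      truth = list(participants = participants,
                   samples = do.call(rbind, samp_truth),
                   elisa = do.call(rbind, elisa_truth)),
      config = cfg), class = "ig_cohort")
  })
}

#' @export
print.ig_cohort <- function(x, ...) {
  cat("Synthetic immunoglobulin-coating cohort\n")
  cat(sprintf("  participants: %d (%d LC, %d nonLC)\n",
              nrow(x$truth$participants),
              sum(x$truth$participants$group == "LC"),
              sum(x$truth$participants$group == "nonLC")))
  cat(sprintf("  samples: %d; events/sample: %d; taxa: %d\n",
              ncol(x$abundance), x$config$events_per_sample, nrow(x$abundance)))
  invisible(x)
}
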