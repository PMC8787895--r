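#' Run the full immunoglobulin-coating pipeline
#'
#' Orchestrates the analysis end to end on a cohort (simulated via
#' [simulate_cohort()] or assembled from tables read with the `read_*`
#' functions): input validation, per-sample gating and coating statistics,
#' ELISA imputation and protein normalization, bound/unbound ratios,
#' participant clustering into LC/nonLC microbiota groups, repeated-measures
#' group association for the four headline outcomes (% IgA bound, IgA coating
#' index, IgA MFI per bacterium, % double-negative), the 2x2 chi-square of
#' IgA-dominant-population presence against microbiota group, and the
#' Kruskal-Wallis + LDA differential-abundance stage on median profiles
#' classed by IgA-dominant presence.
#'
#' @param cohort an `ig_cohort`, or a list with elements `events`,
#'   `controls`, `elisa`, `abundance`, `metadata` (tables in the interchange
#'   schemas).
#' @param stages character subset of
#'   `c("validate","gate","quantify","cluster","associate","lefse")`.
#' @param k,r gating parameters (threshold SD multiplier, ratio rule).
#' @param m imputations per censored ELISA record.
#' @param alpha,lda_threshold,n_boot differential-abundance parameters.
#' @param linkage clustering linkage method.
#' @param zero_policy zero handling for [log10_transform()].
#' @param seed integer seed driving the imputation and bootstrap stages.
#' @param igad_min_frac minimum detected IgAd event fraction for calling an
#'   IgA-dominant population present in a sample (default 0.01 filters out
#'   spurious sub-percent clusters).
#' @return object of class `ig_run_report`: list with per-stage outputs
#'   (`violations`, `coating`, `quant`, `ratios`, `groups`, `association`,
#'   `igad_table`, `igad_chisq`, `lefse`), a `counts` row-count summary and
#'   the echoed `params`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 6,
#'                                      events_per_sample = 400), seed = 11)
#' rep <- run_pipeline(coh, seed = 11)
#' rep$igad_table
#' @export
run_pipeline <- function(cohort,
                         stages = c("validate", "gate", "quantify", "cluster",
                                    "associate", "lefse"),
                         k = 3, r = 3, m = 10, alpha = 0.01,
                         lda_threshold = 2.0, n_boot = 30,
                         linkage = "complete",
                         zero_policy = "halfmin",
                         seed = NULL, igad_min_frac = 0.01) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list(params = list(k = k, r = r, m = m, alpha = alpha,
                            lda_threshold = lda_threshold, n_boot = n_boot,
                            linkage = linkage, zero_policy = zero_policy,
                            seed = seed, igad_min_frac = igad_min_frac))
  md <- cohort$metadata
  md_st <- if ("stain" %in% names(md)) md[md$stain == "stained", ] else md
  timepoints <- sort(unique(md_st$timepoint))

  if ("validate" %in% stages) {
    out$violations <- validate_inputs(events = cohort$events,
                                      controls = cohort$controls,
                                      elisa = cohort$elisa,
                                      abundance = cohort$abundance,
                                      metadata = md_st,
                                      timepoints = timepoints)
    if (nrow(out$violations))
      stop("input validation failed; see the violations table", call. = FALSE)
  }

  if ("gate" %in% stages) {
    out$coating <- gate_cohort(cohort$events, cohort$controls, k = k, r = r)
    ix <- match(out$coating$sample_id, md_st$sample_id)
    out$coating$participant_id <- md_st$participant_id[ix]
    out$coating$timepoint <- md_st$timepoint[ix]
  }

  if ("quantify" %in% stages) {
    out$quant <- quantify_immunoglobulins(cohort$elisa, m = m, seed = seed)
    if (!is.null(out$coating)) {
      iga <- out$quant[out$quant$analyte == "IgA", c("sample_id", "normalized")]
      jn <- merge(out$coating[, c("sample_id", "ci_iga")], iga, by = "sample_id")
      out$ratios <- bound_unbound_ratio(jn$ci_iga, jn$normalized,
                                        sample_id = jn$sample_id,
                                        isotype = "IgA")
    }
  }

  if ("cluster" %in% stages) {
    prof <- median_profiles(cohort$abundance, md_st)
    out$profiles <- prof
    out$groups <- cluster_participants(prof, linkage = linkage)
    out$dominant <- vapply(colnames(cohort$abundance),
                           function(s) dominant_taxon(cohort$abundance[, s])$taxon,
                           character(1))
  }

  if ("associate" %in% stages && !is.null(out$coating) && !is.null(out$groups)) {
    dat <- out$coating
    dat$group <- out$groups$groups$group[match(dat$participant_id,
                                               out$groups$groups$participant_id)]
    outcomes <- list(pct_iga_bound = dat$pct_iga_bound,
                     ci_iga = dat$ci_iga,
                     mfi_per_bact_iga = dat$mfi_per_bact_iga,
                     pct_dn = 100 * dat$frac_dn)
    out$association <- lapply(outcomes, function(vals) {
      long <- data.frame(participant_id = dat$participant_id,
                         timepoint = dat$timepoint, group = dat$group,
                         value = suppressWarnings(
                           log10_transform(vals, zero_policy = zero_policy)))
      fit_repeated_lmm(long, fixed = c("timepoint", "group"))
    })

    # IgA-dominant presence at post-menses timepoints vs microbiota group
    post <- dat[dat$timepoint != timepoints[1], ]
    igad_by_part <- tapply(post$frac_igad >= igad_min_frac, post$participant_id, any)
    gr <- out$groups$groups
    gr$igad_present <- as.logical(igad_by_part[gr$participant_id])
    out$igad_participants <- gr
    tab <- table(factor(gr$igad_present, levels = c(TRUE, FALSE)),
                 factor(gr$group, levels = c("LC", "nonLC")))
    dimnames(tab) <- list(igad = c("present", "absent"),
                          group = c("LC", "nonLC"))
    out$igad_table <- tab
    out$igad_chisq <- tryCatch(pearson_chi_square(tab), error = function(e) {
      warning("chi-square not computable: ", conditionMessage(e))
      NULL
    })
  }

  if ("lefse" %in% stages && !is.null(out$profiles) &&
      !is.null(out$igad_participants)) {
    gr <- out$igad_participants
    cls <- ifelse(gr$igad_present, "IgAd_present", "IgAd_absent")
    if (length(unique(cls)) == 2 && min(table(cls)) >= 2) {
      out$lefse <- run_lefse(t(out$profiles)[gr$participant_id, , drop = FALSE],
                             cls, alpha = alpha, lda_threshold = lda_threshold,
                             n_boot = n_boot, seed = seed)
    } else {
      warning("IgA-dominant classes degenerate; differential abundance skipped")
    }
  }

  out$counts <- data.frame(
    stage = c("events", "controls", "elisa", "samples", "participants"),
    rows = c(nrow(cohort$events), nrow(cohort$controls), nrow(cohort$elisa),
             nrow(md_st), length(unique(md_st$participant_id))))
  class(out) <- "ig_run_report"
  out
}

#' @export
print.ig_run_report <- function(x, ...) {
  cat("igcoat pipeline report\n")
  print(x$counts, row.names = FALSE)
  if (!is.null(x$igad_chisq))
    cat(sprintf("IgAd presence x group: X2 = %.3f, p = %.4f\n",
                x$igad_chisq$statistic, x$igad_chisq$p))
  if (!is.null(x$lefse))
    cat(sprintf("discriminative taxa: %s\n",
                paste(x$lefse$taxon[x$lefse$discriminative], collapse = ", ") %||% ""))
  invisible(x)
}
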