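#' Positivity thresholds from a no-stain control
#'
#' Computes per-channel gating thresholds as the control mean plus `k`
#' standard deviations of the no-stain events, the standard rule for calling
#' an event immunoglobulin-positive against autofluorescence. The sample
#' standard deviation (denominator n - 1) is used.
#'
#' @param no_stain event data frame with `iga_intensity` and `igg_intensity`.
#' @param k multiplier on the control SD (default 3).
#' @return object of class `gating_thresholds`: list with per-channel
#'   `mean`, `sd` and `threshold` (named vectors over `iga`, `igg`) and `k`.
#' @examples
#' ns <- data.frame(iga_intensity = rlnorm(500, log(100), 0.3),
#'                  igg_intensity = rlnorm(500, log(100), 0.3))
#' compute_thresholds(ns, k = 3)$threshold
#' @export
compute_thresholds <- function(no_stain, k = 3) {
  if (!is.data.frame(no_stain) || nrow(no_stain) == 0)
    stop("no-stain control table is empty", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || k < 0)
    stop("k must be a single non-negative multiplier", call. = FALSE)
  m <- c(iga = mean(no_stain$iga_intensity), igg = mean(no_stain$igg_intensity))
  s <- c(iga = sd(no_stain$iga_intensity), igg = sd(no_stain$igg_intensity))
  s[is.na(s)] <- 0
  if (any(s == 0))
    warning("zero-variance control channel; threshold equals control mean")
  structure(list(mean = m, sd = s, threshold = m + k * s, k = k),
            class = "gating_thresholds")
}

# Exact two-means split of a 1-D vector: the optimal 2-cluster solution is a
# contiguous split of the sorted values; scan all n-1 cut points and return
# the assignment minimizing within-cluster sum of squares. Ties take the
# first (leftmost) optimal cut. Returns integer cluster ids (1 = lower).
split_two_means <- function(x) {
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2) return(rep(1L, n))
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  i <- seq_len(n - 1)
  ss_left <- cs2[i] - cs[i]^2 / i
  ss_right <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  cut <- which.min(ss_left + ss_right)
  cl <- integer(n)
  cl[o] <- rep(c(1L, 2L), c(cut, n - cut))
  cl
}

#' Detect bacterial coating populations
#'
#' Classifies events into up to three populations. Events below both channel
#' thresholds form the double-negative (DN) population. Coated events (above
#' threshold on at least one channel, or on both under `coated_rule =
#' "both"`) are split into two candidate clusters by an exact two-means on
#' log(IgA) - log(IgG); the split is accepted as {IgAd, DP} only when the
#' higher-ratio cluster's median IgA/IgG ratio strictly exceeds `r` times the
#' other cluster's ratio, otherwise all coated events form a single DP
#' population. Thresholding is strict: an event exactly at a threshold is
#' not bound.
#'
#' @param events event data frame (`iga_intensity`, `igg_intensity`).
#' @param thr a [compute_thresholds()] result.
#' @param r ratio-quotient multiplier for admitting an IgA-dominant
#'   population (default 3).
#' @param coated_rule `"any"` (default: coated if above >= 1 channel
#'   threshold) or `"both"`.
#' @return object of class `population_model`: list with `populations` (data
#'   frame of label, n, frac, median_iga, median_igg, ratio), `assignment`
#'   (factor over events with levels DN/DP/IgAd) and `flags`.
#' @export
detect_populations <- function(events, thr, r = 3,
                               coated_rule = c("any", "both")) {
  coated_rule <- match.arg(coated_rule)
  if (!is.data.frame(events) || nrow(events) == 0)
    stop("event table is empty", call. = FALSE)
  stopifnot(inherits(thr, "gating_thresholds"))
  above_a <- events$iga_intensity > thr$threshold[["iga"]]
  above_g <- events$igg_intensity > thr$threshold[["igg"]]
  coated <- if (coated_rule == "any") above_a | above_g else above_a & above_g
  assignment <- factor(rep("DN", nrow(events)), levels = c("DN", "DP", "IgAd"))
  flags <- character(0)

  if (!any(coated)) {
    flags <- "no_coated_population"
  } else {
    idx <- which(coated)
    lr <- log(events$iga_intensity[idx]) - log(events$igg_intensity[idx])
    cl <- split_two_means(lr)
    assignment[idx] <- "DP"
    if (length(unique(cl)) == 2) {
      ratio_of <- function(sub) {
        median(events$iga_intensity[idx][sub]) /
          median(events$igg_intensity[idx][sub])
      }
      r1 <- ratio_of(cl == 1L); r2 <- ratio_of(cl == 2L)
      hi <- if (r2 >= r1) 2L else 1L
      if (max(r1, r2) > r * min(r1, r2))
        assignment[idx][cl == hi] <- "IgAd"
    }
  }

  pops <- lapply(levels(assignment), function(lb) {
    sel <- assignment == lb
    if (!any(sel)) return(NULL)
    mi <- median(events$iga_intensity[sel]); mg <- median(events$igg_intensity[sel])
    data.frame(label = lb, n = sum(sel), frac = mean(sel),
               median_iga = mi, median_igg = mg, ratio = mi / mg)
  })
  structure(list(populations = do.call(rbind, pops), assignment = assignment,
                 flags = flags, r = r, coated_rule = coated_rule),
            class = "population_model")
}

#' Per-sample coating statistics
#'
#' Summarizes one stained sample against its thresholds and population model:
#' percent bound per channel (marginal: events strictly above that channel's
#' threshold, regardless of the other channel), the median fluorescence
#' intensity (MFI) of those bound events, the coating index (percent bound x
#' MFI), the MFI per bacterium (MFI / percent bound, undefined when nothing
#' is bound) and the DN/DP/IgAd population fractions.
#'
#' @param events stained event data frame.
#' @param model the [detect_populations()] result for these events.
#' @param thr the [compute_thresholds()] result used for `model`.
#' @return one-row data frame of class `coating_summary` with columns
#'   `sample_id`, `pct_iga_bound`, `pct_igg_bound`, `mfi_iga`, `mfi_igg`,
#'   `ci_iga`, `ci_igg`, `mfi_per_bact_iga`, `mfi_per_bact_igg`, `frac_dn`,
#'   `frac_dp`, `frac_igad`, `undefined_mfi_per_bact` (flag).
#' @examples
#' cfg <- cohort_config(events_per_sample = 2000)
#' ev <- simulate_events(cfg, "P01", "T2", group = "LC", igad = TRUE, seed = 2)
#' thr <- compute_thresholds(ev$no_stain)
#' summarize_sample(ev$stained, detect_populations(ev$stained, thr), thr)
#' @export
summarize_sample <- function(events, model, thr) {
  stopifnot(inherits(model, "population_model"), inherits(thr, "gating_thresholds"))
  if (nrow(events) != length(model$assignment))
    stop("population model does not match the event table", call. = FALSE)
  chan <- function(int, threshold) {
    bound <- int > threshold
    pct <- 100 * mean(bound)
    mfi <- if (any(bound)) median(int[bound]) else 0
    list(pct = pct, mfi = mfi, ci = pct * mfi,
         per_bact = if (pct > 0) mfi / pct else NA_real_)
  }
  a <- chan(events$iga_intensity, thr$threshold[["iga"]])
  g <- chan(events$igg_intensity, thr$threshold[["igg"]])
  fr <- as.numeric(table(model$assignment)) / length(model$assignment)
  out <- data.frame(
    sample_id = if ("sample_id" %in% names(events)) events$sample_id[1] else NA,
    pct_iga_bound = a$pct, pct_igg_bound = g$pct,
    mfi_iga = a$mfi, mfi_igg = g$mfi, ci_iga = a$ci, ci_igg = g$ci,
    mfi_per_bact_iga = a$per_bact, mfi_per_bact_igg = g$per_bact,
    frac_dn = fr[1], frac_dp = fr[2], frac_igad = fr[3],
    undefined_mfi_per_bact = is.na(a$per_bact) || is.na(g$per_bact))
  class(out) <- c("coating_summary", "data.frame")
  out
}

#' Gate every sample of a cohort
#'
#' Applies [compute_thresholds()], [detect_populations()] and
#' [summarize_sample()] to each sample, using that sample's own no-stain
#' control. Samples without a control fall back to the pooled control events
#' of the whole run, with a warning.
#'
#' @param events stained events for all samples (long, with `sample_id`).
#' @param controls no-stain events for all samples (same schema).
#' @param k SD multiplier for thresholds (default 3).
#' @param r ratio-quotient multiplier for the IgA-dominant rule (default 3).
#' @param coated_rule see [detect_populations()].
#' @return data frame with one [summarize_sample()] row per sample.
#' @export
gate_cohort <- function(events, controls, k = 3, r = 3,
                        coated_rule = c("any", "both")) {
  coated_rule <- match.arg(coated_rule)
  ids <- unique(events$sample_id)
  missing_ctrl <- setdiff(ids, unique(controls$sample_id))
  if (length(missing_ctrl))
    warning(sprintf("no no-stain control for %d sample(s); using pooled controls",
                    length(missing_ctrl)))
  ctrl_split <- split(controls, controls$sample_id)
  ev_split <- split(events, events$sample_id)
  out <- lapply(ids, function(id) {
    ns <- ctrl_split[[id]] %||% controls
    thr <- compute_thresholds(ns, k = k)
    ev <- ev_split[[id]]
    summarize_sample(ev, detect_populations(ev, thr, r = r,
                                            coated_rule = coated_rule), thr)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
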