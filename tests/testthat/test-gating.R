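test_that("thresholds are control mean + k SD per channel", {
  # construct controls with exact mean 100 and SD 10 per channel
  z <- as.numeric(scale(rnorm(200)))
  ns <- data.frame(iga_intensity = 100 + 10 * z, igg_intensity = 100 + 10 * z)
  thr <- compute_thresholds(ns, k = 3)
  expect_equal(unname(thr$threshold), c(130, 130))
  expect_equal(unname(compute_thresholds(ns, k = 0)$threshold), c(100, 100))
  expect_error(compute_thresholds(ns[0, ]), "empty")
  expect_warning(
    thr0 <- compute_thresholds(data.frame(iga_intensity = rep(5, 10),
                                          igg_intensity = rep(5, 10))),
    "zero-variance")
  expect_equal(unname(thr0$threshold), c(5, 5))
})

test_that("thresholds agree with an independent two-pass streaming oracle", {
  withr::local_seed(21)
  ns <- data.frame(iga_intensity = rlnorm(5000, log(100), 0.1),
                   igg_intensity = rlnorm(5000, log(100), 0.1))
  # two-pass oracle: accumulate sum, then squared deviations
  oracle <- function(x) {
    m <- sum(x) / length(x)
    m + 3 * sqrt(sum((x - m)^2) / (length(x) - 1))
  }
  thr <- compute_thresholds(ns, k = 3)
  expect_equal(thr$threshold[["iga"]], oracle(ns$iga_intensity),
               tolerance = 0.02)
  expect_equal(thr$threshold[["igg"]], oracle(ns$igg_intensity),
               tolerance = 0.02)
})

test_that("the ratio-quotient rule admits an IgAd population only past 3x", {
  for (q in c(3.5, 2.0)) {
    px <- planted_events(n_dn = 300, n_dp = 1500, n_igad = 700, q = q, seed = 4)
    thr <- compute_thresholds(px$controls)
    model <- detect_populations(px$events, thr, r = 3)
    labs <- as.character(model$populations$label)
    if (q > 3) expect_setequal(labs, c("DN", "DP", "IgAd"))
    else expect_setequal(labs, c("DN", "DP"))
  }
  # single coated cluster -> exactly {DN, DP}
  px <- planted_events(n_dn = 100, n_dp = 400, n_igad = 0, seed = 5)
  thr <- compute_thresholds(px$controls)
  expect_setequal(as.character(detect_populations(px$events, thr)$populations$label),
                  c("DN", "DP"))
})

test_that("planted population fractions are recovered within 0.02 at 20,000 events", {
  cfg <- cohort_config(events_per_sample = 20000)
  cfg$population_params$LC$weights_igad <- c(DN = 0.10, DP = 0.70, IgAd = 0.20)
  ev <- simulate_events(cfg, "P01", "T2", group = "LC", igad = TRUE, seed = 13)
  thr <- compute_thresholds(ev$no_stain)
  sm <- summarize_sample(ev$stained, detect_populations(ev$stained, thr), thr)
  expect_lt(abs(sm$frac_dn - 0.10), 0.02)
  expect_lt(abs(sm$frac_dp - 0.70), 0.02)
  expect_lt(abs(sm$frac_igad - 0.20), 0.02)
})

test_that("coating summary identities hold on every emitted summary", {
  withr::local_seed(31)
  cfg <- small_cfg(events = 1000, n = 3)
  for (s in 1:5) {
    igad <- s %% 2 == 0
    ev <- simulate_events(cfg, "P01", "T2", group = "LC", igad = igad, seed = s)
    thr <- compute_thresholds(ev$no_stain)
    sm <- summarize_sample(ev$stained, detect_populations(ev$stained, thr), thr)
    expect_identical(sm$ci_iga, sm$pct_iga_bound * sm$mfi_iga)
    expect_identical(sm$ci_igg, sm$pct_igg_bound * sm$mfi_igg)
    expect_identical(sm$mfi_per_bact_iga, sm$mfi_iga / sm$pct_iga_bound)
    expect_equal(sm$frac_dn + sm$frac_dp + sm$frac_igad, 1, tolerance = 1e-9)
  }
})

test_that("degenerate all-identical events below threshold gate to pure DN", {
  ev <- data.frame(sample_id = "S", event_id = 1:100,
                   iga_intensity = rep(10, 100), igg_intensity = rep(10, 100))
  ns <- data.frame(iga_intensity = c(90, 100, 110), igg_intensity = c(90, 100, 110))
  thr <- compute_thresholds(ns)
  model <- detect_populations(ev, thr)
  expect_identical(model$flags, "no_coated_population")
  sm <- summarize_sample(ev, model, thr)
  expect_equal(c(sm$pct_iga_bound, sm$pct_igg_bound, sm$ci_iga, sm$ci_igg),
               c(0, 0, 0, 0))
  expect_equal(c(sm$frac_dn, sm$frac_dp, sm$frac_igad), c(1, 0, 0))
  expect_true(sm$undefined_mfi_per_bact)
  expect_true(is.na(sm$mfi_per_bact_iga))
})

test_that("raising k never increases percent bound; scaling behaves homogeneously", {
  withr::local_seed(41)
  cfg <- small_cfg(events = 2000, n = 3)
  ev <- simulate_events(cfg, "P01", "T2", group = "nonLC", igad = TRUE, seed = 6)
  pcts <- sapply(c(1, 2, 3, 4, 6), function(k) {
    thr <- compute_thresholds(ev$no_stain, k = k)
    sm <- summarize_sample(ev$stained, detect_populations(ev$stained, thr), thr)
    sm$pct_iga_bound
  })
  expect_true(all(diff(pcts) <= 0))
  # common scaling of events and controls: MFI and CI scale, pct and fractions invariant
  sc <- 7.3
  scale_tab <- function(df) transform(df, iga_intensity = iga_intensity * sc,
                                      igg_intensity = igg_intensity * sc)
  thr1 <- compute_thresholds(ev$no_stain)
  sm1 <- summarize_sample(ev$stained, detect_populations(ev$stained, thr1), thr1)
  ev2 <- scale_tab(ev$stained); ns2 <- scale_tab(ev$no_stain)
  thr2 <- compute_thresholds(ns2)
  sm2 <- summarize_sample(ev2, detect_populations(ev2, thr2), thr2)
  expect_equal(sm2$pct_iga_bound, sm1$pct_iga_bound)
  expect_equal(c(sm2$frac_dn, sm2$frac_dp, sm2$frac_igad),
               c(sm1$frac_dn, sm1$frac_dp, sm1$frac_igad))
  expect_equal(sm2$mfi_iga, sc * sm1$mfi_iga)
  expect_equal(sm2$ci_iga, sc * sm1$ci_iga)
})

test_that("population assignment matches exhaustive brute force on tiny samples", {
  # brute force: DN by thresholds; best 2-split of coated events over ALL
  # bipartitions by within-cluster SS of the log ratio; then the ratio rule.
  brute_force <- function(events, thr, r = 3) {
    above_a <- events$iga_intensity > thr$threshold[["iga"]]
    above_g <- events$igg_intensity > thr$threshold[["igg"]]
    coated <- which(above_a | above_g)
    assign <- rep("DN", nrow(events))
    if (!length(coated)) return(assign)
    assign[coated] <- "DP"
    m <- length(coated)
    if (m < 2) return(assign)
    lr <- log(events$iga_intensity[coated]) - log(events$igg_intensity[coated])
    best <- NULL; best_ss <- Inf
    for (mask in 1:(2^m - 2)) {
      sel <- as.logical(bitwAnd(mask, 2^(0:(m - 1))))
      ss <- sum((lr[sel] - mean(lr[sel]))^2) + sum((lr[!sel] - mean(lr[!sel]))^2)
      if (ss < best_ss - 1e-12) { best_ss <- ss; best <- sel }
    }
    ratio <- function(ix) median(events$iga_intensity[coated][ix]) /
      median(events$igg_intensity[coated][ix])
    r1 <- ratio(best); r2 <- ratio(!best)
    if (max(r1, r2) > r * min(r1, r2))
      assign[coated][if (r1 >= r2) best else !best] <- "IgAd"
    assign
  }
  for (s in 1:8) {
    px <- planted_events(n_dn = 20, n_dp = 7, n_igad = 5,
                         q = c(2, 5, 12)[s %% 3 + 1], sdlog = 0.3, seed = s)
    thr <- compute_thresholds(px$controls)
    model <- detect_populations(px$events, thr)
    expect_identical(as.character(model$assignment),
                     brute_force(px$events, thr))
  }
})

test_that("recovered fractions have mean absolute error < 0.02 over seeded runs", {
  cfg <- cohort_config(events_per_sample = 20000)
  cfg$population_params$LC$weights_igad <- c(DN = 0.10, DP = 0.70, IgAd = 0.20)
  errs <- sapply(1:10, function(s) {
    ev <- simulate_events(cfg, "P01", "T3", group = "LC", igad = TRUE, seed = s)
    thr <- compute_thresholds(ev$no_stain)
    sm <- summarize_sample(ev$stained, detect_populations(ev$stained, thr), thr)
    abs(c(sm$frac_dn, sm$frac_dp, sm$frac_igad) - c(0.10, 0.70, 0.20))
  })
  expect_lt(mean(rowMeans(errs)), 0.02)
})

test_that("missing controls fall back to pooled controls with a warning", {
  cfg <- small_cfg(events = 500, n = 3)
  coh <- simulate_cohort(cfg, seed = 17)
  ctrl <- coh$controls[coh$controls$sample_id != coh$controls$sample_id[1], ]
  expect_warning(res <- gate_cohort(coh$events, ctrl), "pooled")
  expect_equal(nrow(res), length(unique(coh$events$sample_id)))
})
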