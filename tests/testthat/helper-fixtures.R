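# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data files.

# Small, fast cohort configuration (full study design, fewer events).
small_cfg <- function(events = 300, n = 25, ...) {
  cohort_config(n_participants = n, events_per_sample = events, ...)
}

# Event table with three planted populations at controlled intensities.
# `q` is the IgA/IgG ratio quotient of the second coated cluster relative to
# the first (DP at ratio 1). Controls sit at lognormal(log 100, 0.1), so the
# mean + 3 SD threshold is ~131; coated clusters at 1000 are far above it.
planted_events <- function(n_dn = 50, n_dp = 200, n_igad = 100, q = 10,
                           sdlog = 0.1, seed = 1) {
  withr::local_seed(seed)
  mk <- function(n, mu_a, mu_g)
    data.frame(iga_intensity = rlnorm(n, log(mu_a), sdlog),
               igg_intensity = rlnorm(n, log(mu_g), sdlog))
  ev <- rbind(mk(n_dn, 50, 50),
              mk(n_dp, 1000, 1000),
              if (n_igad > 0) mk(n_igad, 1000 * sqrt(q), 1000 / sqrt(q)))
  ev$sample_id <- "S1"
  ev$event_id <- seq_len(nrow(ev))
  labels <- rep(c("DN", "DP", "IgAd"), c(n_dn, n_dp, n_igad))
  ctrl <- mk(2000, 100, 100)
  ctrl$sample_id <- "S1"; ctrl$event_id <- seq_len(nrow(ctrl))
  list(events = ev, controls = ctrl, labels = labels)
}

# Balanced long-format outcome with a planted LC - nonLC difference `delta`,
# participant random intercepts and iid residual noise.
planted_long <- function(n = 25, delta = 0.33, sd_participant = 0.2,
                         sd_resid = 0.2, tp_effect = c(0.1, 0, 0)) {
  ids <- sprintf("P%02d", seq_len(n))
  group <- rep(c("LC", "nonLC"), c(round(12 / 25 * n), n - round(12 / 25 * n)))
  u <- rnorm(n, 0, sd_participant)
  d <- expand.grid(participant_id = ids, timepoint = c("T1", "T2", "T3"),
                   stringsAsFactors = FALSE)
  j <- match(d$participant_id, ids)
  d$group <- group[j]
  d$value <- 2 + delta * (d$group == "LC") +
    tp_effect[match(d$timepoint, c("T1", "T2", "T3"))] +
    u[j] + rnorm(nrow(d), 0, sd_resid)
  d
}

# Two-class compositional profile matrix with planted marker taxa:
# taxon M1 dominates class 1 (mean share ~0.8), taxon M2 is boosted in
# class 2; remaining taxa are exchangeable Dirichlet noise.
planted_profiles <- function(n1 = 12, n2 = 13, n_taxa = 20) {
  a1 <- rep(1, n_taxa); a1[1] <- 80
  a2 <- rep(1, n_taxa); a2[8] <- 15
  rdir <- function(alpha) { g <- rgamma(length(alpha), alpha); g / sum(g) }
  x <- rbind(t(replicate(n1, rdir(a1))), t(replicate(n2, rdir(a2))))
  colnames(x) <- c("M1", paste0("noise", 2:7), "M2", paste0("noise", 9:n_taxa))
  list(profiles = x, classes = rep(c("c1", "c2"), c(n1, n2)))
}

# Naive O(n^3) complete-linkage agglomeration: returns sorted merge heights.
naive_complete_linkage_heights <- function(d) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(dm[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  sort(heights)
}

# Kruskal-Wallis H by the textbook rank formula with tie correction.
kw_h_oracle <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}
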