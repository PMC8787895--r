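test_that("log10 transform applies the half-minimum zero policy", {
  expect_equal(log10_transform(c(100, 1)), c(2, 0), ignore_attr = TRUE)
  out <- log10_transform(c(0, 10, 100))
  expect_equal(as.numeric(out), c(log10(5), 1, 2))
  expect_identical(attr(out, "replaced"), c(TRUE, FALSE, FALSE))
  expect_true(all(is.na(log10_transform(c(0, 1), zero_policy = "na")[1])))
  expect_error(log10_transform(c(0, 1), zero_policy = "error"), "zero")
  expect_error(log10_transform(-1), "negative")
})

test_that("Bonferroni adjustment is min(1, m p)", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  expect_equal(bonferroni(c(0.2, 0.04), m = 2), c(0.4, 0.08))
  expect_equal(bonferroni(0.2, m = 1), 0.2)
  expect_error(bonferroni(1.2, m = 1), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
})

test_that("the printed 2x2 association reproduces the uncorrected chi-square", {
  # 25 participants: 12 LC / 13 nonLC; 8 with an IgAd population, 7 of them LC
  tab <- matrix(c(7, 5, 1, 12), 2,
                dimnames = list(igad = c("present", "absent"),
                                group = c("LC", "nonLC")))
  res <- pearson_chi_square(tab)
  expect_equal(round(res$p, 3), 0.007)
  # hand O/E oracle
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E))
  expect_equal(res$statistic, 7.354, tolerance = 1e-3)
  expect_equal(res$df, 1)
})

test_that("chi-square is zero under independence and invariant to transposition", {
  res <- pearson_chi_square(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  t1 <- pearson_chi_square(matrix(c(7, 5, 1, 12), 2))
  t2 <- pearson_chi_square(t(matrix(c(7, 5, 1, 12), 2)))
  expect_equal(t1$statistic, t2$statistic)
  expect_equal(t1$p, t2$p)
  expect_error(pearson_chi_square(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("Spearman rho hits the monotone extremes and flags constants", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 9, 20))$rho, 1)
  expect_equal(spearman_cor(1:5, -(1:5))$rho, -1)
  expect_true(spearman_cor(1:5, rep(3, 5))$undefined)
})

test_that("Spearman exact permutation p matches the all-720-permutations oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 2, 5, 4, 9, 7)   # one tie
  got <- spearman_cor(x, y)
  # independent oracle: recursive permutation enumeration + rank-formula rho
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perm_all(v[-i]), function(p) c(v[i], p)))
    out
  }
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) {
    am <- a - mean(a); bm <- b - mean(b)
    sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
  }
  rho_obs <- rho_of(rx, ry)
  rhos <- vapply(perm_all(seq_along(y)), function(ix) rho_of(rx, ry[ix]),
                 numeric(1))
  expect_equal(got$rho, rho_obs)
  expect_equal(got$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
  # large-n path uses the t approximation and agrees with cor.test
  withr::local_seed(5)
  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  ref <- suppressWarnings(cor.test(x2, y2, method = "spearman", exact = FALSE))
  got2 <- spearman_cor(x2, y2)
  expect_equal(got2$rho, unname(ref$estimate))
  expect_equal(got2$p, ref$p.value, tolerance = 1e-6)
})

test_that("paired t handles toy, identical and degenerate inputs", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.0)
  y <- c(1.9, 2.1, 3.9, 5.2, 5.1)
  got <- paired_t(x, y)
  d <- y - x
  expect_equal(got$t, mean(d) / (sd(d) / sqrt(5)))
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  same <- paired_t(x, x)
  expect_equal(c(same$t, same$p), c(0, 1))
  deg <- paired_t(x, x + 1)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$t))
})

test_that("noise-free planted group difference is recovered exactly", {
  withr::local_seed(1)
  d <- planted_long(n = 10, delta = 0.33, sd_participant = 0, sd_resid = 0,
                    tp_effect = c(0, 0, 0))
  res <- suppressWarnings(fit_repeated_lmm(d, fixed = c("timepoint", "group")))
  grp <- res[res$contrast == "group: LC - nonLC", ]
  expect_equal(grp$estimate, 0.33, tolerance = 1e-9)
  expect_lt(grp$ci_high - grp$ci_low, 1e-9)
})

test_that("the unstructured-covariance fit recovers a planted difference", {
  withr::local_seed(2)
  ests <- covered <- logical(0)
  est_vals <- numeric(0)
  for (i in 1:30) {
    d <- planted_long(n = 25, delta = 0.33)
    res <- fit_repeated_lmm(d, fixed = c("timepoint", "group"))
    grp <- res[res$contrast == "group: LC - nonLC", ]
    est_vals <- c(est_vals, grp$estimate)
    covered <- c(covered, grp$ci_low <= 0.33 && 0.33 <= grp$ci_high)
  }
  expect_lt(abs(mean(est_vals) - 0.33), 0.05)
  expect_gte(mean(covered), 0.8)
  # with a single timepoint the model reduces to the two-sample mean difference
  d <- planted_long(n = 20, delta = 0.4)
  d1 <- d[d$timepoint == "T2", ]
  res1 <- suppressWarnings(fit_repeated_lmm(d1, fixed = "group"))
  raw <- mean(d1$value[d1$group == "LC"]) - mean(d1$value[d1$group == "nonLC"])
  expect_equal(res1$estimate[res1$contrast == "group: LC - nonLC"], raw,
               tolerance = 1e-8)
})

test_that("timepoint contrasts carry Bonferroni correction and valid intervals", {
  withr::local_seed(3)
  d <- planted_long(n = 15, delta = 0, tp_effect = c(0.3, 0, -0.1))
  res <- fit_repeated_lmm(d, fixed = c("timepoint", "group"))
  tp <- res[grepl("^timepoint", res$contrast), ]
  expect_equal(nrow(tp), 3)
  expect_equal(tp$p_adjusted, pmin(1, 3 * tp$p_raw))
  expect_true(all(res$ci_low <= res$estimate & res$estimate <= res$ci_high))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))
  # T1 effect of +0.3 appears with the right sign: T2 - T1 and T3 - T1 negative
  expect_lt(tp$estimate[tp$contrast == "timepoint: T2 - T1"], 0)
})

test_that("type-I error of the group test is near nominal under label permutation", {
  withr::local_seed(4)
  hits <- replicate(60, {
    d <- planted_long(n = 25, delta = 0)
    # permute group labels at the participant level
    ids <- unique(d$participant_id)
    glab <- vapply(ids, function(p) d$group[d$participant_id == p][1], "")
    perm <- setNames(sample(glab), ids)
    d$group <- unname(perm[d$participant_id])
    res <- fit_repeated_lmm(d, fixed = c("timepoint", "group"))
    res$p_raw[res$contrast == "group: LC - nonLC"] < 0.05
  })
  expect_lt(mean(hits), 0.18)   # 60 replicates: binomial noise around 0.05
})
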