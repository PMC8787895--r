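#' Log10 transform with zero handling
#'
#' Applies a base-10 logarithm to non-negative outcome values. Zeros cannot
#' be log-transformed; under the default `"halfmin"` policy they are replaced
#' by half the smallest positive observed value of that outcome before
#' transforming (replacements are flagged via the `"replaced"` attribute).
#'
#' @param values non-negative numeric vector.
#' @param zero_policy `"halfmin"` (default), `"na"` (zeros become `NA`) or
#'   `"error"`.
#' @return transformed vector with attribute `replaced` (logical vector).
#' @examples
#' log10_transform(c(0, 10, 100))   # log10(5), 1, 2
#' @export
log10_transform <- function(values, zero_policy = c("halfmin", "na", "error")) {
  zero_policy <- match.arg(zero_policy)
  if (any(values < 0, na.rm = TRUE))
    stop("negative values cannot be log-transformed", call. = FALSE)
  zero <- !is.na(values) & values == 0
  if (any(zero)) {
    if (zero_policy == "error") stop("zero values present", call. = FALSE)
    if (zero_policy == "na") values[zero] <- NA_real_
    if (zero_policy == "halfmin") {
      pos <- values[!is.na(values) & values > 0]
      if (!length(pos)) stop("no positive values to define the half-minimum",
                             call. = FALSE)
      values[zero] <- min(pos) / 2
    }
  }
  out <- log10(values)
  attr(out, "replaced") <- zero
  out
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` for a stated family size `m` (which may exceed the
#' number of p-values supplied).
#'
#' @param p_values p-values in \[0, 1\].
#' @param m family size; defaults to `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p_values)) stop("family size m smaller than number of tests",
                                 call. = FALSE)
  pmin(1, m * p_values)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), the form
#' whose p-value on the study's printed IgA-dominant x microbiota-group
#' counts reproduces the printed 0.007.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic`, `df` (= 1) and `p`.
#' @examples
#' pearson_chi_square(matrix(c(7, 5, 1, 12), 2))
#' @export
pearson_chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integer counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin", call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

# All permutations of 1..n as an n! x n matrix (n <= 9).
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation
#'
#' Spearman's rho with average ranks for ties. For small samples (`n <= 9`)
#' the two-sided p-value is computed by full enumeration of all n!
#' permutations of one variable's ranks (valid under ties, where the
#' classical null tables are not); larger samples use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact permutation
#'   p-value; default `NULL` uses it for `n <= 9`.
#' @return list with `rho`, `p`, `n` and logical `undefined` (constant
#'   input).
#' @export
spearman_cor <- function(x, y, exact = NULL) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of equal length >= 3", call. = FALSE)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  use_exact <- exact %||% (n <= 9)
  if (use_exact) {
    if (n > 9) stop("exact permutation p limited to n <= 9", call. = FALSE)
    perms <- permutations(n)
    rho_perm <- apply(perms, 1, function(ix) cor(rx, ry[ix]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (!is.finite(tt)) 0 else 2 * pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n, undefined = FALSE)
}

#' Paired t test
#'
#' Two-sided paired t test on the differences. Identical vectors give t = 0,
#' p = 1; non-zero constant differences (zero variance) are flagged
#' degenerate with no finite statistic.
#'
#' @param x_pre,x_post paired numeric vectors of equal length >= 2.
#' @return list with `t`, `df`, `p` and logical `degenerate`.
#' @export
paired_t <- function(x_pre, x_post) {
  if (length(x_pre) != length(x_post) || length(x_pre) < 2)
    stop("need paired vectors of equal length >= 2", call. = FALSE)
  d <- x_post - x_pre
  n <- length(d)
  # zero-variance detection robust to floating-point noise in the differences
  if (sd(d) <= 1e-10 * (abs(mean(d)) + 1e-12)) {
    if (all(abs(d) <= 1e-12 * max(abs(x_pre), 1)))
      return(list(t = 0, df = n - 1, p = 1, degenerate = FALSE))
    return(list(t = NA_real_, df = n - 1, p = NA_real_, degenerate = TRUE))
  }
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), n - 1), degenerate = FALSE)
}

# Contrast estimate with CI and p from a fitted model's coef/vcov.
contrast_row <- function(fit, cvec, label, df, conf_level) {
  b <- coef(fit); V <- vcov(fit)
  est <- sum(cvec * b)
  se <- sqrt(drop(t(cvec) %*% V %*% cvec))
  if (se == 0) {
    ci <- c(est, est); p <- if (est == 0) 1 else 0
  } else {
    tq <- qt(1 - (1 - conf_level) / 2, df)
    ci <- est + c(-1, 1) * tq * se
    p <- 2 * pt(-abs(est / se), df)
  }
  data.frame(contrast = label, estimate = est, ci_low = ci[1], ci_high = ci[2],
             p_raw = p)
}

#' Repeated-measures mixed-model association
#'
#' Fits the study's repeated-measures model to a long outcome table: fixed
#' effects for categorical timepoint and (optionally) microbiota group, with
#' an unstructured within-participant covariance over the three timepoints
#' (a free variance per timepoint and a free correlation per timepoint pair),
#' estimated by REML via a marginal [nlme::gls()] model — the classical
#' repeated-measures formulation. On non-convergence the model falls back to
#' a compound-symmetry covariance, and as a last resort to ordinary least
#' squares (which also covers noise-free degenerate data); each fallback
#' warns and is recorded in the result.
#'
#' Emitted contrasts: the group main effect (LC - nonLC, when `group` is in
#' `fixed`) and all three pairwise timepoint differences; the timepoint
#' family is Bonferroni-corrected (family size 3), the group effect is
#' reported uncorrected, as a single pre-specified comparison. Contrast
#' degrees of freedom use the containment convention for repeated measures
#' (participants minus between-subject parameters), so intervals reflect
#' between-participant information rather than the inflated observation
#' count.
#'
#' @param data data frame with columns `participant_id`, `timepoint`,
#'   `value` and (if used) `group`; `value` is typically a log10-transformed
#'   outcome.
#' @param fixed character subset of `c("timepoint", "group")`.
#' @param conf_level confidence level for intervals (default 0.95).
#' @return data frame of class `association_result` with columns `contrast`,
#'   `estimate`, `ci_low`, `ci_high`, `p_raw`, `p_adjusted`, `correction`;
#'   attribute `covariance` records which covariance structure was fitted.
#' @examples
#' d <- expand.grid(participant_id = sprintf("P%02d", 1:10),
#'                  timepoint = c("T1", "T2", "T3"))
#' d$group <- ifelse(as.integer(factor(d$participant_id)) <= 5, "LC", "nonLC")
#' set.seed(1)
#' d$value <- 2 + 0.33 * (d$group == "LC") + rnorm(nrow(d), 0, 0.2)
#' fit_repeated_lmm(d, fixed = c("timepoint", "group"))
#' @export
fit_repeated_lmm <- function(data, fixed = c("timepoint", "group"),
                             conf_level = 0.95) {
  fixed <- match.arg(fixed, c("timepoint", "group"), several.ok = TRUE)
  stopifnot(all(c("participant_id", "timepoint", "value") %in% names(data)))
  data <- data[complete.cases(data[, c("participant_id", "timepoint", "value",
                                       intersect("group", names(data)))]), ]
  tps <- sort(unique(as.character(data$timepoint)))
  data$timepoint <- factor(data$timepoint, levels = tps)
  data$tp_index <- as.integer(data$timepoint)
  data$participant_id <- factor(data$participant_id)
  use_group <- "group" %in% fixed
  if (use_group) {
    data$group <- factor(data$group, levels = c("nonLC", "LC"))
    if (min(table(unique(data[, c("participant_id", "group")])$group)) < 2)
      stop("need >= 2 participants per group", call. = FALSE)
  }
  form <- if (use_group && "timepoint" %in% fixed) value ~ group + timepoint
          else if (use_group) value ~ group else value ~ timepoint

  covariance <- "unstructured"
  fit <- tryCatch(
    nlme::gls(form, data = data,
              correlation = nlme::corSymm(form = ~ tp_index | participant_id),
              weights = nlme::varIdent(form = ~ 1 | timepoint),
              method = "REML",
              control = nlme::glsControl(maxIter = 200, msMaxIter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("unstructured covariance did not converge; falling back to compound symmetry")
    covariance <- "compound_symmetry"
    fit <- tryCatch(
      nlme::gls(form, data = data,
                correlation = nlme::corCompSymm(form = ~ 1 | participant_id),
                method = "REML"),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    warning("gls fits failed; falling back to ordinary least squares")
    covariance <- "ols"
    fit <- lm(form, data = data)
  }
  # degrees of freedom follow the repeated-measures containment convention:
  # contrasts are judged against between-participant variation, so df =
  # participants minus between-subject parameters (intercept, group), not the
  # total observation count.
  n_subj <- nlevels(droplevels(data$participant_id))
  df <- if (inherits(fit, "lm")) df.residual(fit)
        else n_subj - (1L + as.integer(use_group))
  cn <- names(coef(fit))
  zero <- setNames(rep(0, length(cn)), cn)

  rows <- list()
  if (use_group) {
    cv <- zero; cv["groupLC"] <- 1
    rows$group <- cbind(contrast_row(fit, cv, "group: LC - nonLC", df, conf_level),
                        p_adjusted = NA_real_, correction = "none")
    rows$group$p_adjusted <- rows$group$p_raw
  }
  if ("timepoint" %in% fixed && length(tps) >= 2) {
    pairs <- combn(tps, 2, simplify = FALSE)
    tp_rows <- lapply(pairs, function(pr) {
      cv <- zero
      n1 <- paste0("timepoint", pr[1]); n2 <- paste0("timepoint", pr[2])
      if (n2 %in% cn) cv[n2] <- 1          # pr[2] - pr[1] relative to reference
      if (n1 %in% cn) cv[n1] <- -1
      contrast_row(fit, cv, paste0("timepoint: ", pr[2], " - ", pr[1]),
                   df, conf_level)
    })
    tp_rows <- do.call(rbind, tp_rows)
    tp_rows$p_adjusted <- bonferroni(tp_rows$p_raw, m = max(3, nrow(tp_rows)))
    tp_rows$correction <- "bonferroni"
    rows$tp <- tp_rows
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "covariance") <- covariance
  class(res) <- c("association_result", "data.frame")
  res
}
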