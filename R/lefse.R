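#' Kruskal-Wallis screen over taxa
#'
#' Per-taxon Kruskal-Wallis rank-sum test (tie-corrected H, chi-square
#' approximation) comparing two participant classes. For small studies
#' (total n <= 10) the p-value is computed exactly by enumerating all
#' class-label assignments with the observed class sizes. Constant features
#' get p = 1 and are flagged.
#'
#' @param profiles participants x taxa numeric matrix of median relative
#'   abundances (rows = participants).
#' @param classes factor (or character) of length `nrow(profiles)` with two
#'   levels.
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates for total n <= 10.
#' @return data frame with `taxon`, `kw_p`, `constant`.
#' @export
kw_screen <- function(profiles, classes, exact = NULL) {
  profiles <- as.matrix(profiles)
  classes <- factor(as.character(classes))
  if (nlevels(classes) != 2 || any(table(classes) < 1))
    stop("need two non-empty classes", call. = FALSE)
  n <- nrow(profiles)
  use_exact <- exact %||% (n <= 10)
  assignments <- NULL
  if (use_exact) {
    n1 <- sum(classes == levels(classes)[1])
    assignments <- combn(n, n1, simplify = FALSE)
  }
  res <- lapply(colnames(profiles) %||% seq_len(ncol(profiles)), function(tx) {
    x <- profiles[, tx]
    if (length(unique(x)) == 1)
      return(data.frame(taxon = as.character(tx), kw_p = 1, constant = TRUE))
    h_obs <- unname(kruskal.test(x, classes)$statistic)
    if (use_exact) {
      h_perm <- vapply(assignments, function(ix) {
        g <- factor(replace(rep(2L, n), ix, 1L))
        unname(kruskal.test(x, g)$statistic)
      }, numeric(1))
      p <- mean(h_perm >= h_obs - 1e-12)
    } else {
      p <- kruskal.test(x, classes)$p.value
    }
    data.frame(taxon = as.character(tx), kw_p = p, constant = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# One bootstrap LDA effect-size evaluation on the (already rescaled) feature
# matrix X restricted to rows `rows`. Fisher discriminant direction via the
# Moore-Penrose pseudo-inverse of the pooled within-class covariance, so
# collinear or constant features (common in compositions) are handled without
# jitter. Returns per-feature scores following the LEfSe convention:
# (|raw class-mean difference| + |unit-direction component x projected
# class-mean separation|) / 2.
lda_boot_scores <- function(X, cls, rows) {
  Xb <- X[rows, , drop = FALSE]
  cb <- cls[rows]
  lv <- levels(cb)
  m1 <- colMeans(Xb[cb == lv[1], , drop = FALSE])
  m2 <- colMeans(Xb[cb == lv[2], , drop = FALSE])
  d <- m1 - m2
  c1 <- scale(Xb[cb == lv[1], , drop = FALSE], center = TRUE, scale = FALSE)
  c2 <- scale(Xb[cb == lv[2], , drop = FALSE], center = TRUE, scale = FALSE)
  sw <- (crossprod(c1) + crossprod(c2)) / (nrow(Xb) - 2)
  w <- drop(MASS::ginv(sw) %*% d)
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(abs(d))        # no within-class direction: raw difference
  w_unit <- w / nw
  es <- abs(sum(w_unit * d))         # class separation along the axis
  (abs(d) + abs(w_unit) * es) / 2
}

#' Bootstrap LDA effect sizes
#'
#' Scores each taxon by the LEfSe effect-size convention: features are
#' rescaled from relative abundances to the canonical \[0, 1e6\] range, then
#' over `n_boot` stratified bootstrap subsamples (two thirds of each class,
#' both classes always represented) a two-class Fisher linear discriminant is
#' fitted and each taxon scored by the average of its absolute raw class-mean
#' difference and its component of the discriminant-axis separation; the
#' final effect size is `log10(1 + mean score)` over subsamples. The
#' enriched class is the class with the higher overall mean abundance.
#'
#' @inheritParams kw_screen
#' @param taxa character vector of taxa to score (typically the
#'   Kruskal-Wallis passers); default all columns.
#' @param n_boot bootstrap subsamples (default 30).
#' @param boot_fraction fraction of each class drawn per subsample
#'   (default 2/3, at least 2 participants).
#' @param seed optional integer seed.
#' @param rescale multiply relative abundances by this factor before scoring
#'   (default 1e6, the conventional LEfSe feature scale).
#' @return data frame with `taxon`, `lda_log10`, `enriched_class`.
#' @export
lda_effect_size <- function(profiles, classes, taxa = colnames(profiles),
                            n_boot = 30, boot_fraction = 2 / 3, seed = NULL,
                            rescale = 1e6) {
  profiles <- as.matrix(profiles)
  classes <- factor(as.character(classes))
  if (nlevels(classes) != 2 || min(table(classes)) < 2)
    stop("need two classes with >= 2 participants each", call. = FALSE)
  if (!length(taxa))
    return(data.frame(taxon = character(0), lda_log10 = numeric(0),
                      enriched_class = character(0)))
  X <- profiles[, taxa, drop = FALSE] * rescale
  # process classes in order of first appearance so a pure label swap leaves
  # the resample stream (and hence the scores) identical
  lv_order <- unique(as.character(classes))
  idx_by_class <- lapply(lv_order, function(l) which(classes == l))
  n_take <- vapply(idx_by_class,
                   function(ix) max(2L, as.integer(boot_fraction * length(ix))),
                   integer(1))
  with_seed(seed, {
    acc <- matrix(0, n_boot, length(taxa))
    for (b in seq_len(n_boot)) {
      rows <- NULL
      for (attempt in seq_len(10)) {
        rows <- unlist(mapply(function(ix, k) ix[sample.int(length(ix), k)],
                              idx_by_class, n_take, SIMPLIFY = FALSE))
        if (nlevels(droplevels(classes[rows])) == 2) break
        rows <- NULL
      }
      if (is.null(rows))
        stop("degenerate bootstrap: could not draw both classes", call. = FALSE)
      acc[b, ] <- lda_boot_scores(X, classes, rows)
    }
    score <- colMeans(acc)
    m_by_class <- sapply(levels(classes),
                         function(l) colMeans(X[classes == l, , drop = FALSE]))
    if (is.null(dim(m_by_class)))
      m_by_class <- matrix(m_by_class, nrow = 1,
                           dimnames = list(NULL, levels(classes)))
    enriched <- levels(classes)[max.col(m_by_class, ties.method = "first")]
    data.frame(taxon = taxa, lda_log10 = log10(1 + abs(score)),
               enriched_class = enriched, row.names = NULL)
  })
}

#' Differential abundance by Kruskal-Wallis screening + LDA effect size
#'
#' The two-stage procedure used to relate taxa to the appearance of an
#' IgA-dominant bacterial population: taxa are first screened by a per-taxon
#' Kruskal-Wallis test at `alpha`, and the passers are scored by bootstrap
#' linear-discriminant effect size; a taxon is discriminative when its
#' log10 LDA score reaches `lda_threshold`. Only taxa passing the screen are
#' returned (an empty screen yields an empty result).
#'
#' @inheritParams lda_effect_size
#' @param alpha Kruskal-Wallis significance level (default 0.01).
#' @param lda_threshold minimum log10 LDA score (default 2.0).
#' @return data frame of class `lefse_result` sorted by decreasing
#'   `lda_log10`, columns `taxon`, `kw_p`, `passes_kw`, `lda_log10`,
#'   `enriched_class`, `discriminative`; the full per-taxon screen is kept in
#'   attribute `kw_all`.
#' @examples
#' set.seed(1)
#' prof <- matrix(runif(25 * 5), 25, dimnames = list(NULL, paste0("t", 1:5)))
#' prof[, 1] <- prof[, 1] + rep(c(2, 0), c(12, 13))
#' cls <- rep(c("present", "absent"), c(12, 13))
#' run_lefse(prof, cls, seed = 1)
#' @export
run_lefse <- function(profiles, classes, alpha = 0.01, lda_threshold = 2.0,
                      n_boot = 30, boot_fraction = 2 / 3, seed = NULL) {
  kw <- kw_screen(profiles, classes)
  pass <- kw$taxon[kw$kw_p < alpha]
  if (!length(pass)) {
    out <- data.frame(taxon = character(0), kw_p = numeric(0),
                      passes_kw = logical(0), lda_log10 = numeric(0),
                      enriched_class = character(0), discriminative = logical(0))
  } else {
    ld <- lda_effect_size(profiles, classes, taxa = pass, n_boot = n_boot,
                          boot_fraction = boot_fraction, seed = seed)
    out <- merge(kw[kw$taxon %in% pass, c("taxon", "kw_p")], ld, by = "taxon")
    out$passes_kw <- TRUE
    out$discriminative <- out$lda_log10 >= lda_threshold
    out <- out[order(-out$lda_log10), c("taxon", "kw_p", "passes_kw",
                                        "lda_log10", "enriched_class",
                                        "discriminative")]
    rownames(out) <- NULL
  }
  attr(out, "kw_all") <- kw
  class(out) <- c("lefse_result", "data.frame")
  out
}
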