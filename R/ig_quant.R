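#' Multiply impute below-LOD immunoglobulin concentrations
#'
#' Replaces each left-censored concentration with the average of `m`
#' independent draws from the imputation distribution on (0, LOD); the
#' default draws uniformly, the minimal assumption for a value known only to
#' lie below a plate-specific detection limit. Uncensored records pass
#' through unchanged and the censoring flag is preserved so downstream code
#' can trace which values were imputed.
#'
#' @param records ELISA data frame with columns `value`, `lod`, `censored`.
#' @param m number of imputations averaged per censored record (default 10).
#' @param seed optional integer seed; fixed seeds reproduce the imputation.
#' @param draw imputation sampler `function(n, lod)` returning `n` values in
#'   (0, lod); default uniform.
#' @return `records` with censored `value`s filled in (column `imputed` marks
#'   them).
#' @examples
#' rec <- data.frame(value = c(250, NA), lod = c(200, 200),
#'                   censored = c(FALSE, TRUE))
#' impute_below_lod(rec, m = 10, seed = 1)
#' @export
impute_below_lod <- function(records, m = 10, seed = NULL,
                             draw = function(n, lod) runif(n, 0, lod)) {
  stopifnot(is.data.frame(records), m >= 1)
  cens <- which(records$censored)
  if (length(cens) && any(!is.finite(records$lod[cens]) | records$lod[cens] <= 0))
    stop("censored record with missing or non-positive LOD", call. = FALSE)
  records$imputed <- FALSE
  if (!length(cens)) return(records)
  with_seed(seed, {
    records$value[cens] <- vapply(records$lod[cens],
                                  function(l) mean(draw(m, l)), numeric(1))
  })
  records$imputed[cens] <- TRUE
  records
}

#' Normalize concentrations to total protein
#'
#' Corrects for inter- and intra-participant variation in vaginal fluid
#' sampling: normalized = (concentration / total protein) x 1000, i.e. ng of
#' immunoglobulin per 1 mg of total protein.
#'
#' @param records data frame with `value` (ng/ml) and `protein_mg_ml` (> 0).
#' @return `records` with an added `normalized` column (ng / 1 mg protein).
#' @examples
#' normalize_to_protein(data.frame(value = 2, protein_mg_ml = 4))$normalized
#' @export
normalize_to_protein <- function(records) {
  stopifnot(is.data.frame(records))
  if (any(is.na(records$protein_mg_ml)) || any(records$protein_mg_ml <= 0))
    stop("total protein must be > 0 for every record", call. = FALSE)
  if (any(is.na(records$value)))
    stop("missing concentrations; impute below-LOD values first", call. = FALSE)
  records$normalized <- records$value / records$protein_mg_ml * 1000
  records
}

#' Ratio of bound to unbound immunoglobulin
#'
#' Divides the coating index (bound immunoglobulin) by the protein-normalized
#' unbound concentration of the matching isotype. The ratio is flagged
#' undefined when the unbound concentration is zero.
#'
#' @param ci coating index values (>= 0).
#' @param unbound normalized unbound concentrations (>= 0).
#' @param sample_id optional sample labels.
#' @param isotype optional isotype labels (`"IgA"`/`"IgG"`).
#' @return data frame with `ratio` and an `undefined` flag (ratio is `NA`
#'   where undefined).
#' @export
bound_unbound_ratio <- function(ci, unbound, sample_id = NULL, isotype = NULL) {
  if (any(ci < 0, na.rm = TRUE) || any(unbound < 0, na.rm = TRUE))
    stop("coating index and unbound concentration must be non-negative",
         call. = FALSE)
  undef <- unbound == 0
  out <- data.frame(ratio = ifelse(undef, NA_real_, ci / unbound),
                    undefined = undef)
  if (!is.null(sample_id)) out <- cbind(sample_id = sample_id, out)
  if (!is.null(isotype)) out <- cbind(out, isotype = isotype)
  out
}

#' Impute and normalize a full ELISA table
#'
#' Convenience wrapper running [impute_below_lod()] then
#' [normalize_to_protein()] over a cohort ELISA table.
#'
#' @inheritParams impute_below_lod
#' @return the table with `imputed` and `normalized` columns added.
#' @export
quantify_immunoglobulins <- function(records, m = 10, seed = NULL) {
  normalize_to_protein(impute_below_lod(records, m = m, seed = seed))
}
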