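#' Read / write pipeline tables
#'
#' Plain-text interchange for every pipeline table: events and no-stain
#' controls as CSV (`sample_id`, `event_id`, `iga_intensity`,
#' `igg_intensity`), the ELISA panel as CSV (`sample_id`, `analyte`, `value`,
#' `lod`, `censored`, `protein_mg_ml`), abundances as TSV with taxa rows and
#' a leading `taxon` column, and sample metadata as CSV (`sample_id`,
#' `participant_id`, `timepoint`, `stain`). Writers emit exactly what the
#' readers accept; values round-trip at full double precision.
#'
#' @param path file path.
#' @param x table to write (for `write_abundance_tsv`, a taxa x samples
#'   matrix).
#' @return readers return the table (`read_abundance_tsv` a numeric matrix);
#'   writers return `path` invisibly.
#' @name igcoat_io
NULL

#' @rdname igcoat_io
#' @export
read_events_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "event_id", "iga_intensity", "igg_intensity")
  if (!all(need %in% names(df)))
    stop("events CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname igcoat_io
#' @export
write_events_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname igcoat_io
#' @export
read_elisa_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "analyte", "value", "lod", "censored", "protein_mg_ml")
  if (!all(need %in% names(df)))
    stop("elisa CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$censored <- as.logical(df$censored)
  df
}

#' @rdname igcoat_io
#' @export
write_elisa_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname igcoat_io
#' @export
read_abundance_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "taxon")
    stop("abundance TSV must have a leading 'taxon' column", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$taxon
  storage.mode(m) <- "double"
  m
}

#' @rdname igcoat_io
#' @export
write_abundance_tsv <- function(x, path) {
  df <- data.frame(taxon = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname igcoat_io
#' @export
read_metadata_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "participant_id", "timepoint")
  if (!all(need %in% names(df)))
    stop("metadata CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname igcoat_io
#' @export
write_metadata_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `events.csv`, `controls.csv`, `elisa.csv`, `abundance.tsv`,
#' `metadata.csv` and `ground_truth.json` under `dir`.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ig_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events_csv(cohort$events, file.path(dir, "events.csv"))
  write_events_csv(cohort$controls, file.path(dir, "controls.csv"))
  write_elisa_csv(cohort$elisa, file.path(dir, "elisa.csv"))
  write_abundance_tsv(cohort$abundance, file.path(dir, "abundance.tsv"))
  write_metadata_csv(cohort$metadata, file.path(dir, "metadata.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

#' Validate pipeline input tables
#'
#' Schema and range checks on any subset of the pipeline tables: event
#' intensities must be positive and non-missing, abundance columns must sum
#' to 1 (tolerance 1e-6) with no negative entries, ELISA records need
#' positive protein and non-negative LODs, and metadata timepoints must come
#' from the expected label set. Violations are reported with the offending
#' table and row (or sample).
#'
#' @param events,controls,elisa,abundance,metadata tables (data frames /
#'   matrix) or paths to files in the interchange formats; `NULL` entries are
#'   skipped.
#' @param timepoints allowed timepoint labels.
#' @return data frame with columns `table`, `where`, `message`; zero rows
#'   when everything is well-formed.
#' @export
validate_inputs <- function(events = NULL, controls = NULL, elisa = NULL,
                            abundance = NULL, metadata = NULL,
                            timepoints = c("T1", "T2", "T3")) {
  v <- list()
  add <- function(table, where, message)
    v[[length(v) + 1]] <<- data.frame(table = table, where = as.character(where),
                                      message = message)
  chk_events <- function(df, label) {
    if (is.character(df)) df <- read_events_csv(df)
    bad <- which(!is.finite(df$iga_intensity) | !is.finite(df$igg_intensity) |
                   df$iga_intensity <= 0 | df$igg_intensity <= 0)
    for (i in head(bad, 10)) add(label, i, "non-positive or missing intensity")
  }
  if (!is.null(events)) chk_events(events, "events")
  if (!is.null(controls)) chk_events(controls, "controls")
  if (!is.null(elisa)) {
    df <- if (is.character(elisa)) read_elisa_csv(elisa) else elisa
    bad <- which(is.na(df$protein_mg_ml) | df$protein_mg_ml <= 0)
    for (i in head(bad, 10)) add("elisa", i, "non-positive total protein")
    bad <- which(is.na(df$lod) | df$lod < 0)
    for (i in head(bad, 10)) add("elisa", i, "negative or missing LOD")
    bad <- which(!df$censored & (is.na(df$value) | df$value < 0))
    for (i in head(bad, 10)) add("elisa", i, "missing or negative uncensored value")
  }
  if (!is.null(abundance)) {
    m <- if (is.character(abundance)) read_abundance_tsv(abundance) else abundance
    if (any(m < 0)) for (s in head(colnames(m)[colSums(m < 0) > 0], 10))
      add("abundance", s, "negative abundance")
    sums <- colSums(m)
    off <- which(abs(sums - 1) > 1e-6)
    for (s in head(colnames(m)[off], 10))
      add("abundance", s, sprintf("column sums to %.6f, expected 1", sums[s]))
  }
  if (!is.null(metadata)) {
    df <- if (is.character(metadata)) read_metadata_csv(metadata) else metadata
    bad <- which(!df$timepoint %in% timepoints)
    for (i in head(bad, 10))
      add("metadata", i, paste("timepoint outside", paste(timepoints, collapse = "/")))
  }
  if (!length(v))
    return(data.frame(table = character(0), where = character(0),
                      message = character(0)))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
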