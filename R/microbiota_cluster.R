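#' Per-participant median abundance profiles
#'
#' Collapses a taxa x samples relative-abundance matrix to one profile per
#' participant: the per-taxon median over that participant's available
#' samples. These median profiles are the clustering input and the feature
#' matrix of the differential-abundance stage.
#'
#' @param abundance taxa x samples numeric matrix (columns sum to 1).
#' @param metadata data frame mapping `sample_id` to `participant_id` (rows
#'   for other stains are ignored if a `stain` column is present).
#' @return taxa x participants matrix of median relative abundances.
#' @export
median_profiles <- function(abundance, metadata) {
  stopifnot(is.matrix(abundance))
  md <- metadata
  if ("stain" %in% names(md)) md <- md[md$stain == "stained", , drop = FALSE]
  md <- unique(md[, c("sample_id", "participant_id")])
  missing <- setdiff(colnames(abundance), md$sample_id)
  if (length(missing))
    stop("samples without participant mapping: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  part <- md$participant_id[match(colnames(abundance), md$sample_id)]
  ids <- unique(part)
  prof <- vapply(ids, function(p)
    apply(abundance[, part == p, drop = FALSE], 1, median), numeric(nrow(abundance)))
  dimnames(prof) <- list(rownames(abundance), ids)
  prof
}

#' Cluster participants into two microbiota groups
#'
#' Agglomerative hierarchical clustering (complete linkage by default) on
#' Euclidean distances between per-participant median abundance profiles,
#' with the dendrogram cut at its last merge to yield two groups. The group
#' whose members carry the higher mean abundance of the reference taxon
#' (default `L_crispatus`) is labeled `LC`, the other `nonLC`.
#'
#' @param profiles taxa x participants matrix from [median_profiles()].
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson correlation between profiles).
#' @param k number of groups (default 2).
#' @param lc_taxon reference taxon for the LC label.
#' @return object of class `group_assignment`: list with `groups` (data frame
#'   `participant_id`, `group`), `hclust` (the merge tree) and `newick`
#'   (dendrogram as a Newick string).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_participants = 6,
#'                                      events_per_sample = 100), seed = 3)
#' prof <- median_profiles(coh$abundance, coh$metadata)
#' cluster_participants(prof)$groups
#' @export
cluster_participants <- function(profiles, linkage = "complete",
                                 distance = c("euclidean", "correlation"),
                                 k = 2, lc_taxon = "L_crispatus") {
  distance <- match.arg(distance)
  stopifnot(is.matrix(profiles))
  n <- ncol(profiles)
  if (n < k) stop("fewer participants than groups requested", call. = FALSE)
  d <- if (distance == "euclidean") dist(t(profiles))
       else as.dist(1 - cor(profiles))
  hc <- hclust(d, method = linkage)
  cut <- cutree(hc, k = k)
  if (lc_taxon %in% rownames(profiles)) {
    lc_mean <- tapply(profiles[lc_taxon, ], cut, mean)
    lc_cluster <- as.integer(names(which.max(lc_mean)))
  } else {
    lc_cluster <- 1L
  }
  groups <- data.frame(participant_id = colnames(profiles),
                       group = ifelse(cut == lc_cluster, "LC", "nonLC"))
  nwk <- ape::write.tree(ape::as.phylo(hc))
  structure(list(groups = groups, hclust = hc, newick = nwk, k = k,
                 distance = distance, linkage = linkage),
            class = "group_assignment")
}

#' Dominant taxon of an abundance column
#'
#' Returns the taxon with maximal relative abundance. Exact ties are broken
#' by taxon-name order and flagged.
#'
#' @param column named numeric vector of relative abundances.
#' @return list with `taxon` and logical `tie`.
#' @export
dominant_taxon <- function(column) {
  if (is.null(names(column)) || !length(column))
    stop("abundance column must be a named vector", call. = FALSE)
  if (all(column == 0)) stop("all-zero abundance column", call. = FALSE)
  mx <- max(column)
  cand <- sort(names(column)[column == mx])
  list(taxon = cand[1], tie = length(cand) > 1)
}
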