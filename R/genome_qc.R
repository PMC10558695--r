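# Genome quality from single-copy marker genes, and the HQ/MQ tier rules.
#
# Completeness is the fraction of expected single-copy markers seen at least
# once; contamination is the fraction seen in excess (sum of extra copies
# over the marker-set size). This is the two-scalar summary a lineage-aware
# marker search would produce, computed from marker tags on the gene models.

#' Construct a marker set
#'
#' @param marker_ids Character vector of expected single-copy marker ids.
#' @export
marker_set <- function(marker_ids) {
  if (length(marker_ids) == 0L) stopf("marker set must be non-empty")
  if (anyDuplicated(marker_ids)) stopf("marker ids must be unique")
  structure(list(marker_ids = as.character(marker_ids)), class = "marker_set")
}

#' Estimate completeness and contamination of a bin
#'
#' @param bin A `genome_bin` whose gene models carry `marker_id` tags.
#' @param markers A `marker_set`.
#' @return The bin with `completeness` and `contamination` filled in and the
#'   quality `tier` assigned.
#' @export
estimate_quality <- function(bin, markers) {
  stopifnot(inherits(bin, "genome_bin"), inherits(markers, "marker_set"))
  m <- length(markers$marker_ids)
  present <- bin$genes$marker_id[!is.na(bin$genes$marker_id)]
  present <- present[present %in% markers$marker_ids]
  counts <- table(present)
  completeness <- length(counts) / m
  contamination <- sum(pmax(0L, as.integer(counts) - 1L)) / m
  bin$completeness <- completeness
  bin$contamination <- contamination
  bin$tier <- classify_tier(completeness, contamination)
  bin
}

#' Assign the HQ/MQ/FAIL quality tier
#'
#' High quality requires completeness >= 90% and contamination <= 5%;
#' medium quality requires completeness >= 50% and contamination <= 10%;
#' boundaries are inclusive. Vectorized.
#'
#' @param completeness,contamination Fractions in \[0, 1\].
#' @return Character vector over `{"HQ", "MQ", "FAIL"}`.
#' @export
classify_tier <- function(completeness, contamination) {
  stopifnot(is.numeric(completeness), is.numeric(contamination),
            length(completeness) == length(contamination))
  if (any(completeness < 0 | completeness > 1, na.rm = TRUE) ||
      any(contamination < 0, na.rm = TRUE)) {
    stopf("completeness must lie in [0,1] and contamination must be >= 0")
  }
  ifelse(completeness >= 0.90 & contamination <= 0.05, "HQ",
         ifelse(completeness >= 0.50 & contamination <= 0.10, "MQ", "FAIL"))
}

#' Quality report for a set of bins
#'
#' @param bins List of `genome_bin` objects (quality already estimated, or a
#'   `markers` set to estimate it here).
#' @param markers Optional `marker_set`.
#' @return Data frame with `bin_id`, `completeness`, `contamination`, `tier`.
#' @export
quality_report <- function(bins, markers = NULL) {
  if (!is.null(markers)) bins <- lapply(bins, estimate_quality, markers = markers)
  data.frame(
    bin_id = vapply(bins, `[[`, character(1L), "bin_id"),
    completeness = vapply(bins, `[[`, numeric(1L), "completeness"),
    contamination = vapply(bins, `[[`, numeric(1L), "contamination"),
    tier = vapply(bins, `[[`, character(1L), "tier"),
    stringsAsFactors = FALSE
  )
}
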