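# Fragment-based ANI, alignment fraction, and greedy species clustering
# with quality-ranked representative selection.

#' Fragment-based average nucleotide identity between two genomes
#'
#' The smaller genome is cut into non-overlapping fragments of
#' `fragment_length` (trailing sub-fragment remainders are dropped) and
#' each fragment is aligned glocally against the other genome. A fragment
#' maps when its alignment reaches at least 0.8 identity over at least 0.9
#' of the fragment; ANI is the mean identity of mapped fragments and the
#' alignment fraction (AF) is the mapped length over the smaller genome's
#' length, capped at 1.
#'
#' @param a,b `genome_bin` objects.
#' @param fragment_length Fragment size in bp (default 1000).
#' @param min_fragment_identity,min_fragment_coverage Mapping gates
#'   (defaults 0.8 and 0.9).
#' @return A one-row data frame: `genome_a`, `genome_b` (sorted ids),
#'   `ani` (NA when nothing maps), `af`, `n_fragments`, `n_mapped`.
#' @export
compute_ani <- function(a, b, fragment_length = 1000L,
                        min_fragment_identity = 0.8,
                        min_fragment_coverage = 0.9) {
  stopifnot(inherits(a, "genome_bin"), inherits(b, "genome_bin"))
  la <- genome_length(a); lb <- genome_length(b)
  if (la == 0L || lb == 0L) stopf("both genomes must be non-empty")
  # The smaller genome donates fragments, so ANI(a,b) == ANI(b,a).
  if (lb < la || (la == lb && b$bin_id < a$bin_id)) { tmp <- a; a <- b; b <- tmp }
  small_len <- genome_length(a)
  if (fragment_length > small_len) {
    stopf("fragment_length %d exceeds the smaller genome (%d bp)",
          fragment_length, small_len)
  }

  # Concatenate the subject's contigs with N spacers: ambiguity k-mers never
  # seed, so no alignment is anchored across a contig junction.
  subject <- paste(b$contigs, collapse = strrep("N", 50L))
  subject_codes <- kmer_codes(subject, SEED_K_DNA)

  idents <- numeric(0)
  n_frag <- 0L
  for (ct in a$contigs) {
    n <- nchar(ct) %/% fragment_length
    if (n == 0L) next
    for (i in seq_len(n)) {
      frag <- substr(ct, (i - 1L) * fragment_length + 1L, i * fragment_length)
      n_frag <- n_frag + 1L
      aln <- align_pair(frag, subject, mode = "glocal", alphabet = "dna",
                        subject_codes = subject_codes)
      if (!is.null(aln) &&
          aln$identity >= min_fragment_identity &&
          aln$query_coverage >= min_fragment_coverage) {
        idents <- c(idents, aln$identity)
      }
    }
  }
  ids <- sort(c(a$bin_id, b$bin_id))
  data.frame(
    genome_a = ids[1L], genome_b = ids[2L],
    ani = if (length(idents) > 0L) mean(idents) else NA_real_,
    af = min(1, length(idents) * fragment_length / min(la, lb)),
    n_fragments = n_frag, n_mapped = length(idents),
    stringsAsFactors = FALSE
  )
}

# Quality rank used both for cluster seeding and representative selection:
# minimal contamination, then maximal completeness, then maximal genome
# length, then lexicographically smallest bin id.
quality_order <- function(bins) {
  cont <- vapply(bins, `[[`, numeric(1L), "contamination")
  comp <- vapply(bins, `[[`, numeric(1L), "completeness")
  len <- vapply(bins, genome_length, numeric(1L))
  ids <- vapply(bins, `[[`, character(1L), "bin_id")
  if (anyNA(cont) || anyNA(comp)) {
    stopf("quality estimates required for all bins (run estimate_quality)")
  }
  order(cont, -comp, -len, ids)
}

#' Greedy species clustering of genome bins
#'
#' Bins are ranked by quality (contamination ascending, completeness
#' descending, genome length descending, id ascending). The best unassigned
#' bin seeds a cluster and every unassigned bin with `ani >= ani_threshold`
#' and `af >= af_threshold` against the seed joins it; the seed is the
#' cluster representative. Deterministic for fixed input.
#'
#' @param bins List of `genome_bin` with quality estimates.
#' @param ani_threshold,af_threshold Species thresholds (defaults 0.95, 0.30).
#' @param fragment_length Passed to [compute_ani()].
#' @return A list of class `"species_clusters"`: `clusters` (data frame
#'   `cluster_id`, `bin_id`, `is_representative`) and `ani` (pairwise ANI
#'   rows computed along the way).
#' @export
cluster_genomes <- function(bins, ani_threshold = 0.95, af_threshold = 0.30,
                            fragment_length = 1000L) {
  if (is.null(names(bins))) {
    names(bins) <- vapply(bins, `[[`, character(1L), "bin_id")
  }
  ord <- quality_order(bins)
  unassigned <- names(bins)[ord]
  rows <- list()
  ani_rows <- list()
  k <- 0L
  while (length(unassigned) > 0L) {
    k <- k + 1L
    seed_id <- unassigned[1L]
    members <- seed_id
    rest <- setdiff(unassigned, seed_id)
    for (cand in rest) {
      res <- compute_ani(bins[[seed_id]], bins[[cand]], fragment_length)
      ani_rows[[length(ani_rows) + 1L]] <- res
      if (!is.na(res$ani) && res$ani >= ani_threshold && res$af >= af_threshold) {
        members <- c(members, cand)
      }
    }
    rows[[k]] <- data.frame(
      cluster_id = sprintf("SGB%03d", k), bin_id = members,
      is_representative = members == seed_id, stringsAsFactors = FALSE
    )
    unassigned <- setdiff(unassigned, members)
  }
  structure(list(
    clusters = do.call(rbind, rows),
    ani = if (length(ani_rows) > 0L) do.call(rbind, ani_rows) else NULL
  ), class = "species_clusters")
}

#' @export
print.species_clusters <- function(x, ...) {
  cl <- x$clusters
  cat(sprintf("<species_clusters> %d cluster(s) over %d bin(s)\n",
              length(unique(cl$cluster_id)), nrow(cl)))
  invisible(x)
}

#' Pick the representative of a cluster by the quality rule
#'
#' Lexicographic rank: minimal contamination, maximal completeness,
#' maximal genome length, lexicographically smallest bin id.
#'
#' @param bins Named list of `genome_bin` (cluster members, quality
#'   estimated).
#' @return The winning bin id.
#' @export
select_representative <- function(bins) {
  if (is.null(names(bins))) {
    names(bins) <- vapply(bins, `[[`, character(1L), "bin_id")
  }
  names(bins)[quality_order(bins)[1L]]
}
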