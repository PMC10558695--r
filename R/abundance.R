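# Depth-normalized contig abundance, median-of-contigs species abundance,
# and a k-mer containment classification rate.

#' Normalize contig depths to per-sample relative abundances
#'
#' Within each sample, a contig's relative abundance is its depth divided
#' by the summed depth of all contigs in that sample; the result is scale
#' invariant and sums to 1 for non-empty samples. Samples with all-zero
#' depth are kept at zero and listed in the `empty_samples` attribute.
#'
#' @param cov Data frame `contig_id`, `sample_id`, `depth` ((contig,
#'   sample) unique, depth >= 0).
#' @return The table with an added `rel_abundance` column.
#' @export
normalize_depths <- function(cov) {
  need <- c("contig_id", "sample_id", "depth")
  miss <- setdiff(need, names(cov))
  if (length(miss) > 0L) stopf("coverage table lacks: %s", paste(miss, collapse = ", "))
  if (any(cov$depth < 0)) stopf("depths must be non-negative")
  if (anyDuplicated(paste(cov$contig_id, cov$sample_id))) {
    stopf("(contig, sample) pairs must be unique")
  }
  totals <- tapply(cov$depth, cov$sample_id, sum)
  tot <- as.numeric(totals[cov$sample_id])
  cov$rel_abundance <- ifelse(tot > 0, cov$depth / tot, 0)
  attr(cov, "empty_samples") <- names(totals)[totals == 0]
  cov
}

#' Species relative abundance as the median over member contigs
#'
#' Per species and sample, the median of the member contigs' relative
#' abundances (even counts use the mean of the central pair). Medians are
#' reported as-is by default; `renormalize = TRUE` rescales each sample's
#' species values to sum to 1.
#'
#' @param norm Output of [normalize_depths()].
#' @param species_map Data frame `contig_id`, `species_id`.
#' @param renormalize Rescale per sample to sum to 1 (default `FALSE`).
#' @return Species x sample matrix.
#' @export
species_abundance <- function(norm, species_map, renormalize = FALSE) {
  if (!"rel_abundance" %in% names(norm)) stopf("run normalize_depths() first")
  sp <- species_map$species_id[match(norm$contig_id, species_map$contig_id)]
  if (anyNA(sp)) stopf("contig(s) missing from species_map")
  species <- sort(unique(species_map$species_id))
  samples <- sort(unique(norm$sample_id))
  out <- matrix(NA_real_, length(species), length(samples),
                dimnames = list(species, samples))
  for (s in samples) {
    sel <- norm$sample_id == s
    med <- tapply(norm$rel_abundance[sel], sp[sel], median)
    out[names(med), s] <- as.numeric(med)
  }
  if (renormalize) {
    cs <- colSums(out, na.rm = TRUE)
    out <- sweep(out, 2L, ifelse(cs > 0, cs, 1), "/")
  }
  out
}

#' Fraction of reads classified against a set of representative genomes
#'
#' A read is classified when at least `threshold` of its k-mers occur in
#' the k-mer index of the representative genomes (either strand).
#'
#' @param reads Character vector of read sequences.
#' @param representatives List of `genome_bin` (or named character vectors
#'   of contig sequences).
#' @param k K-mer size (default 31).
#' @param threshold Minimum contained k-mer fraction (default 0.6).
#' @return The classified fraction (read-count basis), with per-read
#'   containment in the `containment` attribute.
#' @export
classification_rate <- function(reads, representatives, k = 31L,
                                threshold = 0.6) {
  if (length(reads) == 0L) stopf("read set must be non-empty")
  seqs <- unlist(lapply(representatives, function(r) {
    if (inherits(r, "genome_bin")) unname(r$contigs) else unname(r)
  }))
  index <- unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    c(substring(s, 1:(n - k + 1L), k:n),
      substring(reverse_complement(s), 1:(n - k + 1L), k:n))
  })))
  frac <- vapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) return(0)
    km <- substring(r, 1:(n - k + 1L), k:n)
    mean(km %in% index)
  }, numeric(1L), USE.NAMES = FALSE)
  rate <- mean(frac >= threshold)
  attr(rate, "containment") <- frac
  rate
}

#' Sample reads from a genome (error-free, both strands)
#'
#' Convenience generator for classification-rate experiments.
#'
#' @param bin A `genome_bin`.
#' @param n_reads Number of reads.
#' @param read_length Read length (default 150).
#' @param seed Integer seed.
#' @return Character vector of reads.
#' @export
sample_reads <- function(bin, n_reads, read_length = 150L, seed = 1L) {
  with_seed(seed, {
    lens <- nchar(bin$contigs)
    ok <- which(lens >= read_length)
    if (length(ok) == 0L) stopf("contigs shorter than read_length")
    ci <- ok[sample.int(length(ok), n_reads, replace = TRUE,
                        prob = lens[ok] / sum(lens[ok]))]
    starts <- vapply(ci, function(i) sample.int(lens[i] - read_length + 1L, 1L),
                     integer(1L))
    fwd <- substring(unname(bin$contigs[ci]), starts, starts + read_length - 1L)
    flip <- runif(n_reads) < 0.5
    fwd[flip] <- vapply(fwd[flip], reverse_complement, character(1L),
                        USE.NAMES = FALSE)
    fwd
  })
}
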