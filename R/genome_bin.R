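# GenomeBin container: contigs plus gene models, quality estimates and a
# hierarchical taxon label. Coordinates are 1-based inclusive (GFF3-style)
# throughout the package.

GENE_COLS <- c("gene_id", "contig", "start", "end", "strand",
               "marker_id", "ko", "cog")

#' Construct a genome bin
#'
#' @param bin_id Identifier.
#' @param contigs Named character vector of contig sequences.
#' @param genes Data frame with columns `gene_id`, `contig`, `start`, `end`
#'   (1-based inclusive), `strand` (`"+"`/`"-"`), and optional `marker_id`,
#'   `ko`, `cog` (NA where absent).
#' @param taxon Hierarchical label such as `"p__P1;o__O2;g__G5"`.
#' @param source_sample Sample of origin (free label).
#' @return An object of class `"genome_bin"`.
#' @export
genome_bin <- function(bin_id, contigs, genes = NULL, taxon = NA_character_,
                       source_sample = NA_character_) {
  stopifnot(is.character(bin_id), length(bin_id) == 1L)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
    stopf("contigs must be uniquely named")
  }
  if (is.null(genes)) {
    genes <- data.frame(gene_id = character(), contig = character(),
                        start = integer(), end = integer(),
                        strand = character(), marker_id = character(),
                        ko = character(), cog = character(),
                        stringsAsFactors = FALSE)
  }
  for (col in setdiff(GENE_COLS, names(genes))) genes[[col]] <- NA_character_
  genes <- genes[, GENE_COLS]
  if (nrow(genes) > 0L) {
    clen <- nchar(contigs)[genes$contig]
    if (anyNA(clen) || any(genes$start < 1L) || any(genes$end > clen)) {
      stopf("gene model outside contig bounds in bin '%s'", bin_id)
    }
    if (any(genes$end < genes$start)) stopf("gene end < start in bin '%s'", bin_id)
  }
  structure(list(bin_id = bin_id, contigs = contigs, genes = genes,
                 taxon = taxon, source_sample = source_sample,
                 completeness = NA_real_, contamination = NA_real_,
                 tier = NA_character_),
            class = "genome_bin")
}

#' @export
print.genome_bin <- function(x, ...) {
  cat(sprintf("<genome_bin> %s: %d contig(s), %s bp, %d gene(s), taxon %s\n",
              x$bin_id, length(x$contigs), format(genome_length(x), big.mark = ","),
              nrow(x$genes), x$taxon))
  invisible(x)
}

#' Total length of a bin's contigs
#' @param bin A `genome_bin`.
#' @export
genome_length <- function(bin) sum(nchar(bin$contigs))

# Genome-forward CDS of one gene row; translate with gene$strand.
gene_cds <- function(bin, i) {
  g <- bin$genes[i, ]
  substr(bin$contigs[[g$contig]], g$start, g$end)
}

#' Protein sequences of all genes in a bin
#' @param bin A `genome_bin`.
#' @return Named character vector (gene_id -> protein), stop codon trimmed.
#' @export
bin_proteins <- function(bin) {
  if (nrow(bin$genes) == 0L) return(setNames(character(0), character(0)))
  prot <- vapply(seq_len(nrow(bin$genes)), function(i) {
    p <- translate_cds(gene_cds(bin, i), bin$genes$strand[i])
    sub("\\*$", "", p)
  }, character(1L))
  setNames(prot, bin$genes$gene_id)
}

#' Write a bin's gene models as GFF3
#'
#' @param bin A `genome_bin`.
#' @param path Output path.
#' @export
write_gff3 <- function(bin, path) {
  g <- bin$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$type <- rep("CDS", nrow(g))
  S4Vectors::mcols(gr)$source <- rep("skincat", nrow(g))
  S4Vectors::mcols(gr)$phase <- rep(0L, nrow(g))
  S4Vectors::mcols(gr)$ID <- g$gene_id
  for (col in c("marker_id", "ko", "cog")) {
    S4Vectors::mcols(gr)[[col]] <- g[[col]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3 into the package's gene table
#'
#' @param path GFF3 file.
#' @return Data frame in `genome_bin` gene-table layout.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get_col <- function(nm) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else rep(NA_character_, length(gr))
  }
  data.frame(
    gene_id = get_col("ID"),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    marker_id = get_col("marker_id"),
    ko = get_col("ko"),
    cog = get_col("cog"),
    stringsAsFactors = FALSE
  )
}
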