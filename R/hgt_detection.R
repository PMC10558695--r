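# Best-match horizontal gene transfer detection between taxon groups,
# phylogenetic-incongruence validation, recency split, and COG contrast of
# recent vs non-recent events.

# Taxon group at a 1-based rank of the ";"-separated hierarchy.
taxon_group <- function(taxon, rank = 1L) {
  vapply(strsplit(taxon, ";", fixed = TRUE), function(p) {
    if (length(p) < rank) NA_character_ else p[rank]
  }, character(1L))
}

# All genes of a set of bins in coding orientation, with genome, group and
# COG annotation.
collect_genes <- function(bins, rank = 1L) {
  rows <- lapply(bins, function(b) {
    g <- b$genes
    if (nrow(g) == 0L) return(NULL)
    seqs <- vapply(seq_len(nrow(g)), function(i) {
      s <- gene_cds(b, i)
      if (g$strand[i] == "-") reverse_complement(s) else s
    }, character(1L))
    data.frame(gene_id = g$gene_id, genome = b$bin_id,
               group = taxon_group(b$taxon, rank), cog = g$cog,
               seq = seqs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Detect candidate horizontal gene transfers (best-match approach)
#'
#' For every gene, the best-scoring hit among the genes of all other
#' genomes is found by seeded DNA alignment. A gene is flagged when its
#' best hit lies in a different taxon group at `rank`, with nucleotide
#' identity at least `min_identity`, and its best within-group hit
#' (excluding its own genome) has strictly lower identity. Reciprocally
#' flagged gene pairs are merged into a single event. The donor is the
#' side whose group carries another close homolog of the gene
#' (within-group support); when support does not single out one side the
#' orientation is reported `"ambiguous"` (donor set to the
#' lexicographically smaller genome id for determinism).
#'
#' @param bins List of `genome_bin` with taxon labels.
#' @param rank Taxonomy rank of the analysis groups (default 1 = top
#'   level, the phylum analog).
#' @param min_identity Minimum cross-group nucleotide identity (default 0.9).
#' @return Data frame of events: `gene_id` (recipient copy),
#'   `donor_gene`, `donor_genome`, `recipient_genome`, `donor_taxon`,
#'   `recipient_taxon`, `identity`, `divergence`, `recency`,
#'   `orientation`, `cog`.
#' @export
detect_candidates <- function(bins, rank = 1L, min_identity = 0.9) {
  genes <- collect_genes(bins, rank)
  if (is.null(genes) || length(unique(genes$group)) < 2L) {
    stopf("HGT detection needs at least two taxon groups at rank %d", rank)
  }
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  n <- nrow(genes)
  codes <- lapply(genes$seq, function(s) unique(kmer_codes(s, SEED_K_DNA)))

  # best-hit bookkeeping in plain vectors (identity and score symmetric,
  # so each unordered pair is aligned once)
  bc_j <- rep(NA_integer_, n); bc_id <- numeric(n); bc_sc <- rep(-Inf, n)
  bw_j <- rep(NA_integer_, n); bw_id <- numeric(n); bw_sc <- rep(-Inf, n)
  update_slot <- function(i, j, id, sc, cross) {
    if (cross) {
      better <- sc > bc_sc[i] || (sc == bc_sc[i] && id > bc_id[i]) ||
        (sc == bc_sc[i] && id == bc_id[i] &&
           (is.na(bc_j[i]) || genes$gene_id[j] < genes$gene_id[bc_j[i]]))
      if (better) { bc_j[i] <<- j; bc_id[i] <<- id; bc_sc[i] <<- sc }
    } else {
      better <- sc > bw_sc[i] || (sc == bw_sc[i] && id > bw_id[i]) ||
        (sc == bw_sc[i] && id == bw_id[i] &&
           (is.na(bw_j[i]) || genes$gene_id[j] < genes$gene_id[bw_j[i]]))
      if (better) { bw_j[i] <<- j; bw_id[i] <<- id; bw_sc[i] <<- sc }
    }
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (genes$genome[j] == genes$genome[i]) next
      if (!any(match(codes[[i]], codes[[j]], nomatch = 0L) > 0L)) next
      aln <- align_pair(genes$seq[i], genes$seq[j], mode = "local",
                        alphabet = "dna")
      if (is.null(aln)) next
      cross <- genes$group[j] != genes$group[i]
      update_slot(i, j, aln$identity, aln$score, cross)
      update_slot(j, i, aln$identity, aln$score, cross)
    }
  }
  best_cross <- data.frame(j = bc_j, id = bc_id, score = bc_sc)
  best_within <- data.frame(j = bw_j, id = bw_id, score = bw_sc)

  flagged <- which(!is.na(best_cross$j) &
                     best_cross$id >= min_identity &
                     best_cross$id > best_within$id)
  supported <- best_within$id >= min_identity

  events <- list()
  consumed <- logical(n)
  for (i in flagged) {
    if (consumed[i]) next
    j <- best_cross$j[i]
    reciprocal <- j %in% flagged && !consumed[j] && best_cross$j[j] == i
    if (reciprocal) {
      consumed[c(i, j)] <- TRUE
      sup_i <- supported[i]; sup_j <- supported[j]
      if (xor(sup_i, sup_j)) {
        don <- if (sup_i) i else j
        orientation <- "resolved"
      } else {
        don <- if (genes$genome[i] <= genes$genome[j]) i else j
        orientation <- "ambiguous"
      }
      rec <- if (don == i) j else i
    } else {
      consumed[i] <- TRUE
      rec <- i; don <- j
      orientation <- "resolved"
    }
    div <- 1 - best_cross$id[i]
    events[[length(events) + 1L]] <- data.frame(
      gene_id = genes$gene_id[rec], donor_gene = genes$gene_id[don],
      donor_genome = genes$genome[don], recipient_genome = genes$genome[rec],
      donor_taxon = genes$group[don], recipient_taxon = genes$group[rec],
      identity = best_cross$id[i], divergence = div,
      recency = classify_recency(div), orientation = orientation,
      cog = genes$cog[rec], stringsAsFactors = FALSE
    )
  }
  if (length(events) == 0L) {
    return(data.frame(gene_id = character(), donor_gene = character(),
                      donor_genome = character(), recipient_genome = character(),
                      donor_taxon = character(), recipient_taxon = character(),
                      identity = numeric(), divergence = numeric(),
                      recency = character(), orientation = character(),
                      cog = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, events)
  out[order(out$gene_id), , drop = FALSE]
}

#' Classify HGT recency at a divergence threshold
#'
#' Recent means divergence strictly below the threshold (default 1%).
#'
#' @param divergence Numeric vector of divergences (1 - identity).
#' @param threshold Recency threshold (default 0.01).
#' @return Character vector over `{"recent", "non_recent"}`.
#' @export
classify_recency <- function(divergence, threshold = 0.01) {
  ifelse(divergence < threshold, "recent", "non_recent")
}

#' Validate an HGT candidate by phylogenetic incongruence
#'
#' Builds a neighbor-joining species tree from (1 - ANI) distances and a
#' neighbor-joining gene tree from protein distances of the candidate
#' gene's homologs (its best hit in each genome at >= `min_homolog_id`
#' identity). The candidate is validated when the recipient's gene sits
#' topologically closer (fewer internal edges) to the donor group in the
#' gene tree than the recipient genome does in the species tree. With
#' fewer than four genomes or four homologs the comparison is degenerate
#' and the candidate passes as `"unvalidated"`.
#'
#' @param event One event row from [detect_candidates()].
#' @param bins List of `genome_bin`.
#' @param rank Taxonomy rank of the analysis groups.
#' @param ani_table Optional precomputed pairwise ANI data frame
#'   (`genome_a`, `genome_b`, `ani`); computed on demand otherwise.
#' @param min_homolog_id Minimum protein identity for homolog inclusion
#'   (default 0.3).
#' @return `"validated"`, `"rejected"`, or `"unvalidated"`.
#' @export
validate_phylogeny <- function(event, bins, rank = 1L, ani_table = NULL,
                               min_homolog_id = 0.3) {
  if (is.null(names(bins))) {
    names(bins) <- vapply(bins, `[[`, character(1L), "bin_id")
  }
  if (length(bins) < 4L) return("unvalidated")

  ids <- names(bins)
  if (is.null(ani_table)) {
    pairs <- utils::combn(ids, 2L)
    ani_table <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      compute_ani(bins[[pairs[1L, k]]], bins[[pairs[2L, k]]])
    }))
  }
  dm <- matrix(0.5, length(ids), length(ids), dimnames = list(ids, ids))
  diag(dm) <- 0
  for (r in seq_len(nrow(ani_table))) {
    d <- if (is.na(ani_table$ani[r])) 0.5 else 1 - ani_table$ani[r]
    dm[ani_table$genome_a[r], ani_table$genome_b[r]] <- d
    dm[ani_table$genome_b[r], ani_table$genome_a[r]] <- d
  }
  sp_tree <- ape::nj(stats::as.dist(dm))

  # homologs of the recipient's gene copy: best protein hit per genome
  rec_bin <- bins[[event$recipient_genome]]
  gi <- match(event$gene_id, rec_bin$genes$gene_id)
  if (is.na(gi)) stopf("event gene '%s' not found in recipient", event$gene_id)
  prot_of <- function(bin, i) {
    p <- translate_cds(gene_cds(bin, i), bin$genes$strand[i])
    sub("\\*$", "", p)
  }
  qprot <- prot_of(rec_bin, gi)
  homologs <- c(setNames(qprot, event$recipient_genome))
  for (gid in setdiff(ids, event$recipient_genome)) {
    b <- bins[[gid]]
    best <- NULL
    for (i in seq_len(nrow(b$genes))) {
      p <- prot_of(b, i)
      aln <- align_pair(qprot, p, mode = "local", alphabet = "protein")
      if (is.null(aln) || aln$identity < min_homolog_id) next
      if (is.null(best) || aln$score > best$score) {
        best <- list(score = aln$score, prot = p)
      }
    }
    if (!is.null(best)) homologs[gid] <- best$prot
  }
  if (length(homologs) < 4L) return("unvalidated")

  hd <- matrix(0, length(homologs), length(homologs),
               dimnames = list(names(homologs), names(homologs)))
  for (i in seq_along(homologs)) {
    for (j in seq_along(homologs)) {
      if (j <= i) next
      aln <- align_pair(homologs[[i]], homologs[[j]], mode = "local",
                        alphabet = "protein")
      d <- if (is.null(aln)) 1 else 1 - aln$identity
      hd[i, j] <- d; hd[j, i] <- d
    }
  }
  gene_tree <- ape::nj(stats::as.dist(hd))

  topo_dist <- function(tree, from, to_set) {
    tree$edge.length <- rep(1, nrow(tree$edge))
    cd <- ape::cophenetic.phylo(tree)
    to_set <- intersect(to_set, rownames(cd))
    if (length(to_set) == 0L || !from %in% rownames(cd)) return(NA_real_)
    min(cd[from, to_set])
  }
  donor_group_genomes <- ids[taxon_group(
    vapply(bins, `[[`, character(1L), "taxon"), rank
  ) == event$donor_taxon]
  donor_group_genomes <- setdiff(donor_group_genomes, event$recipient_genome)

  gd <- topo_dist(gene_tree, event$recipient_genome, donor_group_genomes)
  sd <- topo_dist(sp_tree, event$recipient_genome, donor_group_genomes)
  if (is.na(gd) || is.na(sd)) return("unvalidated")
  if (gd < sd) "validated" else "rejected"
}

#' COG-category contrast of recent vs non-recent HGT events
#'
#' Per COG letter seen in the events, a 2x2 table (recent/non-recent x
#' in-category/other) is tested with a two-sided Fisher exact test;
#' p-values are Benjamini-Hochberg adjusted and the table is sorted by
#' adjusted p.
#'
#' @param events Event table from [detect_candidates()] (columns `recency`,
#'   `cog`).
#' @return Data frame `cog`, `n_recent`, `n_nonrecent`, `odds_ratio`,
#'   `p_value`, `q_value`.
#' @export
cog_contrast <- function(events) {
  ev <- events[!is.na(events$cog), , drop = FALSE]
  cogs <- sort(unique(ev$cog))
  if (length(cogs) == 0L) {
    return(data.frame(cog = character(), n_recent = integer(),
                      n_nonrecent = integer(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  rec <- ev$recency == "recent"
  out <- do.call(rbind, lapply(cogs, function(cg) {
    a <- sum(rec & ev$cog == cg)        # recent, in category
    b <- sum(rec & ev$cog != cg)
    c_ <- sum(!rec & ev$cog == cg)
    d <- sum(!rec & ev$cog != cg)
    ft <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))
    data.frame(cog = cg, n_recent = a, n_nonrecent = c_,
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  }))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out[order(out$q_value, out$p_value, out$cog), , drop = FALSE]
}
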