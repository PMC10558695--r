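# Seed-deterministic synthetic metagenome generator with known ground truth:
# species genomes at controlled ANI, bins with controlled completeness and
# contamination, coverage tables from known abundances, pileups with
# controlled mutation composition, planted horizontal transfers, and BGCs
# with planted shared genes.

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

random_protein <- function(n) {
  aa <- setdiff(PROTEIN_CHARS, c("X", "*"))
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# A random gene of `n_codons` codons: ATG, then sense codons, then a stop.
random_gene <- function(n_codons) {
  sense <- names(codon_aa_table())[codon_aa_table() != "*"]
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate a set of synthetic species genomes with gene models
#'
#' Each species gets an independent random genome: genes of 300-1500 nt
#' (ATG-initiated, stop-terminated, both strands) separated by 50-500 nt
#' intergenic spacers, split across `n_contigs` contigs and padded to
#' exactly `genome_length` bp. The first `n_markers` genes are tagged as
#' single-copy markers (same marker ids in every species); every gene gets
#' a KO id and a COG letter. Taxon labels form a hierarchy of depth
#' `taxon_tree_depth` whose top level has `n_phyla` groups and whose leaf
#' level is unique per species.
#'
#' @param n_species Number of species (>= 1).
#' @param genome_length Genome length in bp (default 60000); must
#'   accommodate the sampled genes and spacers.
#' @param n_genes_per_genome Genes per genome (default 25).
#' @param taxon_tree_depth Depth of the taxon hierarchy (default 3).
#' @param seed Integer seed; same seed gives byte-identical output.
#' @param n_contigs Contigs per genome (default 4).
#' @param n_markers Number of marker-tagged genes (default
#'   `min(100, n_genes_per_genome)`).
#' @param n_phyla Number of top-level taxon groups (default 2).
#' @return List with `bins` (list of `genome_bin`), `markers`
#'   (a `marker_set`), and `truth` (a `simulation_truth`).
#' @export
generate_species_set <- function(n_species, genome_length = 60000L,
                                 n_genes_per_genome = 25L,
                                 taxon_tree_depth = 3L, seed = 1L,
                                 n_contigs = 4L,
                                 n_markers = min(100L, n_genes_per_genome),
                                 n_phyla = 2L) {
  stopifnot(n_species >= 1L, n_genes_per_genome >= 1L, taxon_tree_depth >= 1L,
            n_markers <= n_genes_per_genome, n_phyla >= 1L)
  mean_gene <- 900L
  if (genome_length < 10L * mean_gene) {
    stopf("genome_length must be at least %d (10 x mean gene length)",
          10L * mean_gene)
  }
  with_seed(seed, {
    taxa <- make_taxon_paths(n_species, taxon_tree_depth, n_phyla)
    bins <- vector("list", n_species)
    for (i in seq_len(n_species)) {
      bins[[i]] <- generate_one_genome(
        bin_id = sprintf("sp%02d", i), genome_length = genome_length,
        n_genes = n_genes_per_genome, n_contigs = n_contigs,
        n_markers = n_markers, taxon = taxa[i]
      )
    }
  })
  names(bins) <- vapply(bins, `[[`, character(1L), "bin_id")
  truth <- simulation_truth(
    species_assignments = setNames(names(bins), names(bins)),
    seed = seed
  )
  list(bins = bins,
       markers = marker_set(sprintf("M%03d", seq_len(n_markers))),
       truth = truth)
}

make_taxon_paths <- function(n_species, depth, n_phyla) {
  prefix <- function(j, d) {
    if (d == 3L) c("p", "o", "g")[j] else paste0("t", j)
  }
  vapply(seq_len(n_species), function(i) {
    phylum <- (i - 1L) %% n_phyla + 1L
    rank_in_phylum <- (i - 1L) %/% n_phyla + 1L
    labels <- character(depth)
    labels[1L] <- sprintf("%s__P%d", prefix(1L, depth), phylum)
    if (depth >= 2L) {
      for (j in seq(2L, depth)) {
        if (j == depth) {
          labels[j] <- sprintf("%s__G%d", prefix(j, depth), i)
        } else {
          grp <- (rank_in_phylum - 1L) %/% 2L^(depth - j) + 1L
          labels[j] <- sprintf("%s__P%d.%d.%d", prefix(j, depth), phylum, j, grp)
        }
      }
    }
    paste(labels, collapse = ";")
  }, character(1L))
}

generate_one_genome <- function(bin_id, genome_length, n_genes, n_contigs,
                                n_markers, taxon) {
  n_codons <- sample(100:500, n_genes, replace = TRUE)   # genes 300-1500 nt
  gene_seqs <- vapply(n_codons, random_gene, character(1L))
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  contig_of <- sort(rep_len(seq_len(n_contigs), n_genes))
  spacers <- sample(50:500, n_genes + n_contigs, replace = TRUE)

  need <- sum(nchar(gene_seqs)) + sum(spacers)
  if (need > genome_length) {
    stopf("infeasible gene packing: genome_length must be at least %d", need)
  }
  # Spread the slack over the trailing spacer of each contig.
  pad <- genome_length - need
  pad_per_contig <- rep(pad %/% n_contigs, n_contigs)
  pad_per_contig[n_contigs] <- pad_per_contig[n_contigs] + pad %% n_contigs

  contigs <- character(n_contigs)
  genes <- NULL
  si <- 1L
  gi <- 0L
  for (cj in seq_len(n_contigs)) {
    parts <- character(0)
    pos <- 0L
    for (g in which(contig_of == cj)) {
      gi <- gi + 1L
      sp <- spacers[si]; si <- si + 1L
      parts <- c(parts, random_dna(sp))
      pos <- pos + sp
      seq_g <- if (strands[g] == "+") gene_seqs[g] else reverse_complement(gene_seqs[g])
      parts <- c(parts, seq_g)
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("%s_g%03d", bin_id, gi),
        contig = sprintf("%s_c%d", bin_id, cj),
        start = pos + 1L, end = pos + nchar(seq_g), strand = strands[g],
        marker_id = if (gi <= n_markers) sprintf("M%03d", gi) else NA_character_,
        ko = sprintf("K%05d", sample(1:200, 1L)),
        cog = sample(c("C", "E", "G", "J", "K", "L", "M", "P", "T", "V"), 1L),
        stringsAsFactors = FALSE
      ))
      pos <- pos + nchar(seq_g)
    }
    tail_sp <- spacers[si] + pad_per_contig[cj]; si <- si + 1L
    parts <- c(parts, random_dna(tail_sp))
    contigs[cj] <- paste(parts, collapse = "")
  }
  names(contigs) <- sprintf("%s_c%d", bin_id, seq_len(n_contigs))
  genome_bin(bin_id, contigs, genes, taxon = taxon, source_sample = "synthetic")
}

#' Container for the generator's ground truth
#'
#' @param species_assignments Named character vector, genome id -> species id.
#' @param true_abundances Species x sample matrix of fractions (columns sum
#'   to 1), or `NULL`.
#' @param planted_snvs Data frame of planted variants, or `NULL`.
#' @param planted_hgts Data frame of planted transfers, or `NULL`.
#' @param shared_bgc_genes Data frame of planted shared BGC gene pairs, or `NULL`.
#' @param seed The generator seed.
#' @export
simulation_truth <- function(species_assignments, true_abundances = NULL,
                             planted_snvs = NULL, planted_hgts = NULL,
                             shared_bgc_genes = NULL, seed = NA_integer_) {
  if (!is.null(true_abundances)) {
    sums <- colSums(true_abundances)
    if (any(abs(sums - 1) > 1e-9)) stopf("true abundances must sum to 1 per sample")
  }
  structure(list(species_assignments = species_assignments,
                 true_abundances = true_abundances,
                 planted_snvs = planted_snvs,
                 planted_hgts = planted_hgts,
                 shared_bgc_genes = shared_bgc_genes,
                 seed = seed),
            class = "simulation_truth")
}

#' Derive a genome at a controlled ANI from a reference genome
#'
#' Substitutes exactly `round((1 - target_ani) * genome_length)` positions
#' (uniformly placed, each to a different base), preserving gene
#' coordinates.
#'
#' @param bin Source `genome_bin`.
#' @param target_ani Fraction in \[0.8, 1\].
#' @param seed Integer seed.
#' @param new_id Identifier of the derived bin.
#' @export
mutate_to_ani <- function(bin, target_ani, seed,
                          new_id = paste0(bin$bin_id, "_d")) {
  if (!is_fraction(target_ani) || target_ani < 0.8) {
    stopf("target_ani must lie in [0.8, 1]")
  }
  L <- genome_length(bin)
  n_sub <- round((1 - target_ani) * L)
  contigs <- bin$contigs
  if (n_sub > 0L) {
    with_seed(seed, {
      pos <- sample.int(L, n_sub)
      offsets <- c(0L, cumsum(nchar(contigs)))
      for (ci in seq_along(contigs)) {
        p <- pos[pos > offsets[ci] & pos <= offsets[ci + 1L]] - offsets[ci]
        if (length(p) == 0L) next
        chars <- strsplit(contigs[[ci]], "")[[1L]]
        chars[p] <- vapply(chars[p], function(b) {
          sample(setdiff(BASES, b), 1L)
        }, character(1L))
        contigs[[ci]] <- paste(chars, collapse = "")
      }
    })
  }
  names(contigs) <- sub(bin$bin_id, new_id, names(bin$contigs), fixed = TRUE)
  genes <- bin$genes
  if (nrow(genes) > 0L) {
    genes$contig <- sub(bin$bin_id, new_id, genes$contig, fixed = TRUE)
    genes$gene_id <- sub(bin$bin_id, new_id, genes$gene_id, fixed = TRUE)
  }
  genome_bin(new_id, contigs, genes, taxon = bin$taxon,
             source_sample = bin$source_sample)
}

#' Build a bin with controlled completeness and contamination
#'
#' Marker completeness is realized exactly by dropping randomly chosen
#' marker gene models; contamination is realized exactly by adding foreign
#' contigs (gene plus 50 bp flanks, cut from a random genome of
#' `foreign_pool`) that duplicate markers already present.
#'
#' @param bin Source `genome_bin`.
#' @param completeness Target completeness in (0, 1].
#' @param contamination Target contamination in \[0, 0.2].
#' @param foreign_pool List of `genome_bin` to draw contaminant contigs from
#'   (required when `contamination > 0`).
#' @param markers The `marker_set` used for quality estimation.
#' @param seed Integer seed.
#' @param new_id Identifier of the produced bin.
#' @export
make_bin <- function(bin, completeness, contamination, foreign_pool = list(),
                     markers, seed, new_id = paste0(bin$bin_id, "_bin")) {
  if (!is_fraction(completeness) || completeness <= 0) {
    stopf("completeness must lie in (0, 1]")
  }
  if (!is.numeric(contamination) || contamination < 0 || contamination > 0.2) {
    stopf("contamination must lie in [0, 0.2]")
  }
  if (contamination > 0 && length(foreign_pool) == 0L) {
    stopf("foreign_pool must be non-empty when contamination > 0")
  }
  m <- length(markers$marker_ids)
  n_keep <- round(completeness * m)
  n_dup <- round(contamination * m)

  with_seed(seed, {
    genes <- bin$genes
    contigs <- bin$contigs
    marker_rows <- which(genes$marker_id %in% markers$marker_ids)
    if (length(marker_rows) < n_keep) {
      stopf("bin has only %d of %d markers; cannot reach completeness %.2f",
            length(marker_rows), m, completeness)
    }
    drop <- sample(marker_rows, length(marker_rows) - n_keep)
    if (length(drop) > 0L) genes <- genes[-drop, , drop = FALSE]

    if (n_dup > 0L) {
      present <- genes$marker_id[!is.na(genes$marker_id)]
      dup_markers <- sample(present, n_dup)
      for (j in seq_along(dup_markers)) {
        donor <- foreign_pool[[sample.int(length(foreign_pool), 1L)]]
        drow <- which(donor$genes$marker_id == dup_markers[j])
        if (length(drow) == 0L) {
          stopf("foreign pool lacks marker '%s'", dup_markers[j])
        }
        dg <- donor$genes[drow[1L], ]
        flank <- 50L
        cs <- max(1L, dg$start - flank)
        ce <- min(nchar(donor$contigs[[dg$contig]]), dg$end + flank)
        cname <- sprintf("%s_contam%d", new_id, j)
        contigs[[cname]] <- substr(donor$contigs[[dg$contig]], cs, ce)
        genes <- rbind(genes, data.frame(
          gene_id = sprintf("%s_contamg%d", new_id, j), contig = cname,
          start = dg$start - cs + 1L, end = dg$end - cs + 1L,
          strand = dg$strand, marker_id = dg$marker_id, ko = dg$ko,
          cog = dg$cog, stringsAsFactors = FALSE
        ))
      }
    }
  })
  out <- genome_bin(new_id, contigs, genes, taxon = bin$taxon,
                    source_sample = bin$source_sample)
  estimate_quality(out, markers)
}

#' Simulate a per-contig, per-sample coverage table from known abundances
#'
#' Contig depth is `depth_scale x species abundance x lognormal noise`
#' with unit mean and coefficient of variation `noise_cv` (exactly 1 when
#' `noise_cv = 0`), identical in expectation for all contigs of a species.
#'
#' @param true_abundances Species x sample matrix (columns sum to 1).
#' @param bins Named list of `genome_bin`, one per species (names are the
#'   rownames of `true_abundances`).
#' @param depth_scale Mean depth multiplier (default 50).
#' @param noise_cv Lognormal coefficient of variation (default 0.1).
#' @param seed Integer seed.
#' @return Data frame `contig_id`, `sample_id`, `depth`.
#' @export
simulate_coverage <- function(true_abundances, bins, depth_scale = 50,
                              noise_cv = 0.1, seed = 1L) {
  stopifnot(!is.null(rownames(true_abundances)), !is.null(colnames(true_abundances)))
  if (!all(rownames(true_abundances) %in% names(bins))) {
    stopf("every species in true_abundances needs a genome in `bins`")
  }
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    rows <- list()
    for (s in colnames(true_abundances)) {
      for (sp in rownames(true_abundances)) {
        ab <- true_abundances[sp, s]
        cn <- names(bins[[sp]]$contigs)
        noise <- if (noise_cv == 0) rep(1, length(cn))
                 else rlnorm(length(cn), meanlog = -sdlog^2 / 2, sdlog = sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = cn, sample_id = s,
          depth = depth_scale * ab * noise, stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a read pileup with planted SNVs of controlled composition
#'
#' Plants `n_snvs` variants at distinct positions with class composition
#' drawn multinomially from the supplied targets; each planted variant's
#' codon class is re-verified against [classify_snv()] before emission.
#' Every site receives exactly `depth` reads; non-variant alleles acquire
#' sequencing errors at `error_rate` per read.
#'
#' @param bin A `genome_bin`.
#' @param n_snvs Number of variants to plant.
#' @param nonsyn_fraction_target,intergenic_fraction_target Target class
#'   fractions (synonymous takes the remainder; the two must sum to <= 1).
#' @param depth Reads per site (default 50).
#' @param alt_freq_range Planted alt-allele frequency range (default
#'   `c(0.2, 0.8)`).
#' @param error_rate Per-read error probability (default 0.001).
#' @param seed Integer seed.
#' @return List with `pileup` (contig, pos, ref, A, C, G, T) and
#'   `planted` (contig, pos, ref, alt, class, freq).
#' @export
simulate_pileup <- function(bin, n_snvs, nonsyn_fraction_target = 0.35,
                            intergenic_fraction_target = 0.1, depth = 50L,
                            alt_freq_range = c(0.2, 0.8), error_rate = 0.001,
                            seed = 1L) {
  syn_target <- 1 - nonsyn_fraction_target - intergenic_fraction_target
  if (syn_target < -1e-12) stopf("class fraction targets must sum to <= 1")
  pool <- snv_site_classes(bin)
  with_seed(seed, {
    cls <- sample(c("synonymous", "nonsynonymous", "intergenic"), n_snvs,
                  replace = TRUE,
                  prob = c(syn_target, nonsyn_fraction_target,
                           intergenic_fraction_target))
    planted <- NULL
    used <- character(0)
    for (cl in c("synonymous", "nonsynonymous", "intergenic")) {
      n_cl <- sum(cls == cl)
      if (n_cl == 0L) next
      cand <- pool[pool$class == cl &
                     !(paste(pool$contig, pool$pos) %in% used), , drop = FALSE]
      # one candidate per position, then sample positions
      cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
      cand <- cand[!duplicated(paste(cand$contig, cand$pos)), , drop = FALSE]
      if (nrow(cand) < n_cl) {
        stopf("not enough %s sites to plant %d variants", cl, n_cl)
      }
      pick <- cand[seq_len(n_cl), , drop = FALSE]
      used <- c(used, paste(pick$contig, pick$pos))
      planted <- rbind(planted, pick)
    }
    # verify planted classes against the codon-level classifier
    for (i in seq_len(nrow(planted))) {
      got <- classify_snv(bin, planted$contig[i], planted$pos[i], planted$alt[i])
      if (!identical(got, planted$class[i])) {
        stopf("internal inconsistency: planted %s reclassified as %s",
              planted$class[i], got)
      }
    }
    planted$freq <- runif(nrow(planted), alt_freq_range[1L], alt_freq_range[2L])
    emit_pileup(bin, planted, depth, error_rate)
  })
}

#' Simulate SNVs under a selection model
#'
#' Proposes substitutions uniformly over all possible coding substitutions
#' and accepts nonsynonymous proposals with probability
#' `nonsyn_acceptance` (synonymous proposals are always accepted), so the
#' expected site-normalized pN/pS equals `nonsyn_acceptance` and equals 1
#' under neutrality.
#'
#' @inheritParams simulate_pileup
#' @param nonsyn_acceptance Acceptance probability of nonsynonymous
#'   proposals in \[0, 1] (1 = neutral).
#' @return As [simulate_pileup()].
#' @export
simulate_selection_pileup <- function(bin, n_snvs, nonsyn_acceptance = 1,
                                      depth = 50L, alt_freq_range = c(0.2, 0.8),
                                      error_rate = 0, seed = 1L) {
  stopifnot(is_fraction(nonsyn_acceptance))
  pool <- snv_site_classes(bin)
  pool <- pool[pool$class != "intergenic", , drop = FALSE]
  with_seed(seed, {
    keep_w <- ifelse(pool$class == "nonsynonymous", nonsyn_acceptance, 1)
    # sample distinct positions with acceptance-weighted probability
    ord <- sample.int(nrow(pool), prob = keep_w + 1e-12)
    pool <- pool[ord, , drop = FALSE]
    pool <- pool[!duplicated(paste(pool$contig, pool$pos)), , drop = FALSE]
    if (nrow(pool) < n_snvs) stopf("genome too small for %d SNVs", n_snvs)
    planted <- pool[seq_len(n_snvs), , drop = FALSE]
    planted$freq <- runif(n_snvs, alt_freq_range[1L], alt_freq_range[2L])
    emit_pileup(bin, planted, depth, error_rate)
  })
}

# Shared pileup emission given planted variants (runs inside with_seed).
emit_pileup <- function(bin, planted, depth, error_rate) {
  pile <- NULL
  for (cn in names(bin$contigs)) {
    refs <- strsplit(bin$contigs[[cn]], "")[[1L]]
    n <- length(refs)
    m <- matrix(0L, n, 4L, dimnames = list(NULL, BASES))
    ref_idx <- match(refs, BASES)
    ok <- !is.na(ref_idx)
    m[cbind(which(ok), ref_idx[ok])] <- depth
    if (error_rate > 0) {
      n_err <- rbinom(n, depth, error_rate)
      for (i in which(n_err > 0L & ok)) {
        alts <- setdiff(1:4, ref_idx[i])
        pick <- sample(alts, n_err[i], replace = TRUE)
        for (a in pick) m[i, a] <- m[i, a] + 1L
        m[i, ref_idx[i]] <- m[i, ref_idx[i]] - n_err[i]
      }
    }
    pl <- planted[planted$contig == cn, , drop = FALSE]
    for (i in seq_len(nrow(pl))) {
      p <- pl$pos[i]
      ac <- rbinom(1L, depth, pl$freq[i])
      ai <- match(pl$alt[i], BASES)
      ri <- match(pl$ref[i], BASES)
      m[p, ] <- 0L
      m[p, ri] <- depth - ac
      m[p, ai] <- ac
    }
    pile <- rbind(pile, data.frame(contig = cn, pos = seq_len(n), ref = refs,
                                   A = m[, 1L], C = m[, 2L], G = m[, 3L],
                                   T = m[, 4L], stringsAsFactors = FALSE))
  }
  rownames(pile) <- NULL
  rownames(planted) <- NULL
  list(pileup = pile,
       planted = planted[, c("contig", "pos", "ref", "alt", "class", "freq")])
}

#' Plant a horizontal gene transfer
#'
#' Copies a donor gene into a random intergenic gap of the recipient
#' genome, with `divergence` fraction of its positions substituted, and
#' updates the recipient's gene models (downstream coordinates shift by the
#' inserted length).
#'
#' @param donor,recipient `genome_bin` objects.
#' @param gene_id A gene of the donor.
#' @param divergence Fraction of transferred positions to substitute.
#' @param seed Integer seed.
#' @return List with `recipient` (modified bin) and `event` (a one-row data
#'   frame: donor, recipient, donor_gene, recipient_gene, divergence).
#' @export
plant_hgt <- function(donor, recipient, gene_id, divergence = 0, seed = 1L) {
  gi <- match(gene_id, donor$genes$gene_id)
  if (is.na(gi)) stopf("gene '%s' not found in donor", gene_id)
  stopifnot(is_fraction(divergence))
  g <- donor$genes[gi, ]
  cds <- gene_cds(donor, gi)          # genome-forward; keep donor's strand

  with_seed(seed, {
    n_sub <- round(divergence * nchar(cds))
    if (n_sub > 0L) {
      pos <- sample.int(nchar(cds), n_sub)
      chars <- strsplit(cds, "")[[1L]]
      chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(BASES, b), 1L),
                           character(1L))
      cds <- paste(chars, collapse = "")
    }
    # choose an intergenic insertion point on a random recipient contig
    cn <- sample(names(recipient$contigs), 1L)
    rg <- recipient$genes[recipient$genes$contig == cn, , drop = FALSE]
    rg <- rg[order(rg$start), , drop = FALSE]
    gaps_lo <- c(0L, rg$end)            # insert after this coordinate
    gaps_hi <- c(rg$start, nchar(recipient$contigs[[cn]]) + 1L)
    ok <- which(gaps_hi - gaps_lo > 2L)
    gpick <- ok[sample.int(length(ok), 1L)]
    at <- gaps_lo[gpick] + (gaps_hi[gpick] - gaps_lo[gpick]) %/% 2L
  })

  seq_old <- recipient$contigs[[cn]]
  ins_len <- nchar(cds)
  recipient$contigs[[cn]] <- paste0(substr(seq_old, 1L, at), cds,
                                    substr(seq_old, at + 1L, nchar(seq_old)))
  shift <- recipient$genes$contig == cn & recipient$genes$start > at
  recipient$genes$start[shift] <- recipient$genes$start[shift] + ins_len
  recipient$genes$end[shift] <- recipient$genes$end[shift] + ins_len
  new_gene <- sprintf("%s_hgt_%s", recipient$bin_id, gene_id)
  recipient$genes <- rbind(recipient$genes, data.frame(
    gene_id = new_gene, contig = cn, start = at + 1L, end = at + ins_len,
    strand = g$strand, marker_id = NA_character_, ko = g$ko, cog = g$cog,
    stringsAsFactors = FALSE
  ))
  rebuilt <- genome_bin(recipient$bin_id, recipient$contigs, recipient$genes,
                        taxon = recipient$taxon,
                        source_sample = recipient$source_sample)
  rebuilt$completeness <- recipient$completeness
  rebuilt$contamination <- recipient$contamination
  rebuilt$tier <- recipient$tier
  list(recipient = rebuilt,
       event = data.frame(donor = donor$bin_id, recipient = recipient$bin_id,
                          donor_gene = gene_id, recipient_gene = new_gene,
                          divergence = divergence, stringsAsFactors = FALSE))
}

#' Generate synthetic BGCs with planted shared genes
#'
#' Creates `n_families` families of `clusters_per_family` clusters. All
#' clusters of a family carry a mutated copy (about 5% amino-acid
#' substitutions) of each of the family's `n_shared` core proteins; the
#' remaining `genes_per_cluster - n_shared` proteins are cluster-private
#' random sequences, so clusters share genes within families and not
#' across them.
#'
#' @param n_families Number of planted families.
#' @param clusters_per_family Clusters per family.
#' @param genes_per_cluster Proteins per cluster.
#' @param n_shared Shared core proteins per family (default 1).
#' @param protein_length Length of generated proteins (default 200).
#' @param genome_ids Optional vector of genome ids to assign round-robin.
#' @param seed Integer seed.
#' @return List with `bgcs` (list of `bgc_record`) and `truth` (data frame
#'   of planted shared pairs: bgc_a, bgc_b, family).
#' @export
generate_bgc_set <- function(n_families = 2L, clusters_per_family = 3L,
                             genes_per_cluster = 5L, n_shared = 1L,
                             protein_length = 200L, genome_ids = NULL,
                             seed = 1L) {
  stopifnot(n_shared < genes_per_cluster)
  classes <- c("NRPS", "PKS", "terpene", "betalactone", "siderophore")
  with_seed(seed, {
    bgcs <- list()
    truth <- NULL
    for (f in seq_len(n_families)) {
      cores <- replicate(n_shared, random_protein(protein_length))
      cls <- classes[(f - 1L) %% length(classes) + 1L]
      ids <- sprintf("bgc_f%d_c%d", f, seq_len(clusters_per_family))
      for (cix in seq_len(clusters_per_family)) {
        shared <- vapply(cores, function(p) mutate_protein(p, 0.05), character(1L))
        private <- replicate(genes_per_cluster - n_shared,
                             random_protein(protein_length))
        prots <- setNames(
          c(shared, private),
          sprintf("%s_p%d", ids[cix], seq_len(genes_per_cluster))
        )
        gid <- if (is.null(genome_ids)) sprintf("genome_f%d", f)
               else genome_ids[((f - 1L) * clusters_per_family + cix - 1L) %%
                                 length(genome_ids) + 1L]
        bgcs[[ids[cix]]] <- bgc_record(ids[cix], gid, cls, prots)
      }
      pairs <- utils::combn(ids, 2L)
      truth <- rbind(truth, data.frame(bgc_a = pairs[1L, ], bgc_b = pairs[2L, ],
                                       family = f, stringsAsFactors = FALSE))
    }
    list(bgcs = bgcs, truth = truth)
  })
}

mutate_protein <- function(prot, rate) {
  aa <- setdiff(PROTEIN_CHARS, c("X", "*"))
  n_sub <- round(rate * nchar(prot))
  if (n_sub == 0L) return(prot)
  pos <- sample.int(nchar(prot), n_sub)
  chars <- strsplit(prot, "")[[1L]]
  chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(aa, b), 1L),
                       character(1L))
  paste(chars, collapse = "")
}
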