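# SNV calling from pileups, codon-aware classification, Nei-Gojobori site
# counting and depth-corrected pN/pS selection-pressure statistics.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

codon_aa_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::getGeneticCode("11")
    cache
  }
})

# Amino acid of a codon (coding orientation); NA if it contains ambiguity.
codon_aa <- function(codon) {
  aa <- codon_aa_table()[codon]
  unname(aa)
}

#' Call SNVs from a pileup table
#'
#' Implements the standard metagenomic SNV filters: a position needs at
#' least `min_depth` reads, the minor (non-reference) allele at least
#' `min_freq` frequency, and the allele count must be inconsistent with
#' sequencing error at FDR `fdr`. The error null is binomial: each read is
#' miscalled to a specific alternative base with probability
#' `error_rate / 3`; p-values are the upper-tail probability of the observed
#' alternative count, Benjamini-Hochberg adjusted across every non-zero
#' alternative allele tested. The most frequent non-reference base is
#' reported as the alt.
#'
#' @param pileup Data frame with columns `contig`, `pos` (1-based), `ref`,
#'   and read counts `A`, `C`, `G`, `T`.
#' @param min_depth Minimum total depth (default 5).
#' @param min_freq Minimum alt-allele frequency (default 0.05).
#' @param fdr FDR ceiling on the adjusted p-value (default 1e-6).
#' @param error_rate Per-base sequencing error rate of the null (default 0.001).
#' @return Data frame of SNV records: `contig`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_count`, `alt_freq`, `p_value`, `q_value`.
#' @export
call_snvs <- function(pileup, min_depth = 5L, min_freq = 0.05, fdr = 1e-6,
                      error_rate = 0.001) {
  need <- c("contig", "pos", "ref", "A", "C", "G", "T")
  miss <- setdiff(need, names(pileup))
  if (length(miss) > 0L) stopf("pileup lacks column(s): %s", paste(miss, collapse = ", "))
  bad <- which(!pileup$ref %in% BASES |
                 !is.finite(pileup$A) | !is.finite(pileup$C) |
                 !is.finite(pileup$G) | !is.finite(pileup$T))
  if (length(bad) > 0L) stopf("malformed pileup row %d", bad[1L])

  counts <- as.matrix(pileup[, BASES])
  depth <- rowSums(counts)
  ref_idx <- match(pileup$ref, BASES)
  # Long format: one test per (site, non-reference base) with count > 0.
  tests <- NULL
  for (b in seq_along(BASES)) {
    sel <- which(ref_idx != b & counts[, b] > 0L)
    if (length(sel) == 0L) next
    tests <- rbind(tests, data.frame(
      row = sel, alt = BASES[b], count = counts[sel, b],
      depth = depth[sel], stringsAsFactors = FALSE
    ))
  }
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      alt = character(), depth = numeric(), alt_count = numeric(),
                      alt_freq = numeric(), p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(tests)) return(empty)

  tests$p <- pbinom(tests$count - 1, tests$depth, error_rate / 3,
                    lower.tail = FALSE)
  tests$q <- p.adjust(tests$p, method = "BH")

  # Keep, per site, the most frequent non-reference base (ties: A<C<G<T).
  ord <- order(tests$row, -tests$count, match(tests$alt, BASES))
  tests <- tests[ord, ]
  top <- tests[!duplicated(tests$row), ]

  keep <- top$depth >= min_depth &
    top$count / top$depth >= min_freq &
    top$q <= fdr
  top <- top[keep, ]
  if (nrow(top) == 0L) return(empty)
  out <- data.frame(
    contig = pileup$contig[top$row],
    pos = pileup$pos[top$row],
    ref = pileup$ref[top$row],
    alt = top$alt,
    depth = top$depth,
    alt_count = top$count,
    alt_freq = top$count / top$depth,
    p_value = top$p,
    q_value = top$q,
    stringsAsFactors = FALSE
  )
  out[order(out$contig, out$pos), , drop = FALSE]
}

# Locate the gene containing (contig, pos); NA if intergenic. Gene models
# are assumed non-overlapping.
find_gene <- function(genes, contig, pos) {
  hit <- which(genes$contig == contig & genes$start <= pos & genes$end >= pos)
  if (length(hit) == 0L) NA_integer_ else hit[1L]
}

#' Classify an SNV as synonymous, nonsynonymous or intergenic
#'
#' Substitutes the alternative base into the containing codon
#' (strand-resolved) and compares the translated amino acids.
#'
#' @param bin A `genome_bin` providing contig sequences and gene models.
#' @param contig Contig id.
#' @param pos 1-based position on the contig.
#' @param alt Alternative base (genome-forward orientation).
#' @return `"synonymous"`, `"nonsynonymous"`, `"intergenic"`, or `NA` when
#'   the containing codon carries ambiguity codes.
#' @export
classify_snv <- function(bin, contig, pos, alt) {
  if (!contig %in% names(bin$contigs)) stopf("unknown contig '%s'", contig)
  clen <- nchar(bin$contigs[[contig]])
  if (pos < 1L || pos > clen) {
    stopf("position %d beyond contig '%s' (length %d)", pos, contig, clen)
  }
  if (!alt %in% BASES) stopf("alt must be one of A/C/G/T")
  gi <- find_gene(bin$genes, contig, pos)
  if (is.na(gi)) return("intergenic")
  g <- bin$genes[gi, ]
  seq <- bin$contigs[[contig]]

  if (g$strand == "+") {
    off <- pos - g$start                   # 0-based offset into CDS
    codon_start <- g$start + (off %/% 3L) * 3L
    codon <- substr(seq, codon_start, codon_start + 2L)
    w <- off %% 3L + 1L                    # position within codon
    alt_codon <- codon
    substr(alt_codon, w, w) <- alt
  } else {
    off <- g$end - pos                     # 0-based offset into CDS (coding dir)
    codon_end <- g$end - (off %/% 3L) * 3L
    fwd_codon <- substr(seq, codon_end - 2L, codon_end)
    codon <- reverse_complement(fwd_codon)
    w <- off %% 3L + 1L
    alt_codon <- codon
    substr(alt_codon, w, w) <- COMPLEMENT[[alt]]
  }
  aa_ref <- codon_aa(codon)
  aa_alt <- codon_aa(alt_codon)
  if (is.na(aa_ref) || is.na(aa_alt)) return(NA_character_)
  if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
}

# Enumerate the class of every possible substitution in a bin:
# data frame (contig, pos, ref, alt, class). Coding positions are expanded
# per gene; positions outside genes are intergenic. Codons containing
# ambiguity codes are skipped; intergenic ambiguity positions are skipped.
snv_site_classes <- function(bin) {
  aa_tab <- codon_aa_table()
  out <- vector("list", nrow(bin$genes) + length(bin$contigs))
  k <- 0L
  covered <- lapply(bin$contigs, function(s) logical(nchar(s)))

  for (i in seq_len(nrow(bin$genes))) {
    g <- bin$genes[i, ]
    covered[[g$contig]][g$start:g$end] <- TRUE
    cds_fwd <- substr(bin$contigs[[g$contig]], g$start, g$end)
    cds <- if (g$strand == "+") cds_fwd else reverse_complement(cds_fwd)
    nc <- nchar(cds) %/% 3L
    L <- nc * 3L                             # trailing partial codon excluded
    if (L == 0L) next
    codon_idx <- rep(seq_len(nc), each = 3L)
    codons <- substring(cds, seq(1L, L, 3L), seq(3L, L, 3L))
    aa_codon <- unname(aa_tab[codons])       # NA for ambiguity-containing codons
    ref_coding <- strsplit(substr(cds, 1L, L), "")[[1L]]
    w_in_codon <- rep(1:3, times = nc)
    valid <- !is.na(aa_codon[codon_idx]) & ref_coding %in% BASES

    rows <- vector("list", 3L)
    for (a in 1:3) {
      # a-th alternative base per position (the 3 bases != ref, in ACGT order)
      alt_of <- function(r) if (r %in% BASES) setdiff(BASES, r)[a] else NA_character_
      alts <- vapply(ref_coding, alt_of, character(1L), USE.NAMES = FALSE)
      alt_codons <- paste0(
        substr(codons[codon_idx], 1L, w_in_codon - 1L),
        alts,
        substr(codons[codon_idx], w_in_codon + 1L, 3L)
      )
      cls <- ifelse(aa_codon[codon_idx] == unname(aa_tab[alt_codons]),
                    "synonymous", "nonsynonymous")
      if (g$strand == "+") {
        gpos <- g$start + seq_len(L) - 1L
        galt <- alts
        gref <- ref_coding
      } else {
        gpos <- g$end - seq_len(L) + 1L
        galt <- unname(COMPLEMENT[alts])
        gref <- unname(COMPLEMENT[ref_coding])
      }
      rows[[a]] <- data.frame(contig = g$contig, pos = gpos, ref = gref,
                              alt = galt, class = cls, gene_id = g$gene_id,
                              stringsAsFactors = FALSE)[valid, , drop = FALSE]
    }
    k <- k + 1L
    out[[k]] <- do.call(rbind, rows)
  }

  for (cn in names(bin$contigs)) {
    free <- which(!covered[[cn]])
    if (length(free) == 0L) next
    refs <- strsplit(bin$contigs[[cn]], "")[[1L]][free]
    ok <- refs %in% BASES
    free <- free[ok]; refs <- refs[ok]
    if (length(free) == 0L) next
    rows <- lapply(1:3, function(a) {
      alts <- vapply(refs, function(r) setdiff(BASES, r)[a], character(1L),
                     USE.NAMES = FALSE)
      data.frame(contig = cn, pos = free, ref = refs, alt = alts,
                 class = "intergenic", gene_id = NA_character_,
                 stringsAsFactors = FALSE)
    })
    k <- k + 1L
    out[[k]] <- do.call(rbind, rows)
  }
  df <- do.call(rbind, out[seq_len(k)])
  df[order(df$contig, df$pos, df$alt), , drop = FALSE]
}

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' Each coding position contributes the fraction of its three possible
#' substitutions that are synonymous to `syn_sites` and the remainder to
#' `nonsyn_sites`. Reference stop codons are included (a stop-to-sense
#' change counts as nonsynonymous); codons with ambiguity codes are
#' excluded.
#'
#' @param bin A `genome_bin`.
#' @param by_gene If `TRUE`, return per-gene counts as a data frame.
#' @return Named numeric vector `c(syn_sites=, nonsyn_sites=)`, or a data
#'   frame with `gene_id`, `syn_sites`, `nonsyn_sites` when `by_gene`.
#' @export
count_sites <- function(bin, by_gene = FALSE) {
  pool <- snv_site_classes(bin)
  pool <- pool[pool$class != "intergenic", , drop = FALSE]
  if (nrow(pool) == 0L) {
    if (by_gene) return(data.frame(gene_id = character(), syn_sites = numeric(),
                                   nonsyn_sites = numeric()))
    return(c(syn_sites = 0, nonsyn_sites = 0))
  }
  if (by_gene) {
    syn <- tapply(pool$class == "synonymous", pool$gene_id, sum) / 3
    non <- tapply(pool$class == "nonsynonymous", pool$gene_id, sum) / 3
    ids <- sort(unique(pool$gene_id))
    return(data.frame(gene_id = ids, syn_sites = as.numeric(syn[ids]),
                      nonsyn_sites = as.numeric(non[ids]),
                      stringsAsFactors = FALSE))
  }
  c(syn_sites = sum(pool$class == "synonymous") / 3,
    nonsyn_sites = sum(pool$class == "nonsynonymous") / 3)
}

#' Annotate called SNVs with codon class, gene and COG
#'
#' @param snvs SNV table from [call_snvs()].
#' @param bin The reference `genome_bin`.
#' @return `snvs` with added `snv_class`, `gene_id`, `cog` columns.
#' @export
annotate_snvs <- function(snvs, bin) {
  if (nrow(snvs) == 0L) {
    snvs$snv_class <- character(0); snvs$gene_id <- character(0)
    snvs$cog <- character(0)
    return(snvs)
  }
  cls <- character(nrow(snvs)); gid <- character(nrow(snvs))
  for (i in seq_len(nrow(snvs))) {
    cls[i] <- classify_snv(bin, snvs$contig[i], snvs$pos[i], snvs$alt[i])
    g <- find_gene(bin$genes, snvs$contig[i], snvs$pos[i])
    gid[i] <- if (is.na(g)) NA_character_ else bin$genes$gene_id[g]
  }
  snvs$snv_class <- cls
  snvs$gene_id <- gid
  snvs$cog <- bin$genes$cog[match(gid, bin$genes$gene_id)]
  snvs
}

#' Selection-pressure statistics per species and skin environment
#'
#' Per sample, SNV counts are depth-corrected (divided by the sample's mean
#' depth over the species) and site-normalized: pN' = n_nonsyn /
#' (depth x nonsyn_sites), pS' = n_syn / (depth x syn_sites). The headline
#' pN/pS (reported as `ka_ks`) of a species in an environment is the mean
#' of the per-sample pN'/pS' ratios (`method = "per_sample"`), or the ratio
#' of environment-pooled depth-corrected counts (`method = "pooled"`).
#' Samples with zero synonymous SNVs are excluded from the mean and counted
#' in `n_excluded`. A raw, site-free count ratio `raw_ratio`
#' (n_nonsyn / n_syn, pooled) is also reported; under neutrality it sits
#' near the nonsynonymous/synonymous site ratio (about 3), whereas the
#' site-normalized statistic sits at 1.
#'
#' @param snvs Data frame of annotated SNVs with columns `sample_id`,
#'   `species_id`, `snv_class`.
#' @param sites Data frame with `species_id`, `syn_sites`, `nonsyn_sites`.
#' @param metadata Data frame with `sample_id`, `environment`
#'   (sebaceous/moist/dry).
#' @param depths Data frame with `species_id`, `sample_id`, `mean_depth`.
#' @param method `"per_sample"` (default) or `"pooled"`.
#' @return Data frame per species x environment with counts, `ka_ks`,
#'   `raw_ratio`, `n_samples`, `n_excluded`, and a `selection` label
#'   (negative if ka_ks < 1, positive if > 1).
#' @export
selection_pressure <- function(snvs, sites, metadata, depths,
                               method = c("per_sample", "pooled")) {
  method <- match.arg(method)
  envs <- c("sebaceous", "moist", "dry")
  bad <- setdiff(unique(metadata$environment), envs)
  if (length(bad) > 0L) {
    stopf("unknown environment label(s): %s", paste(bad, collapse = ", "))
  }
  snvs$environment <- metadata$environment[match(snvs$sample_id, metadata$sample_id)]
  if (anyNA(snvs$environment)) stopf("SNV sample(s) missing from metadata")

  out <- list()
  for (sp in sort(unique(snvs$species_id))) {
    st <- sites[sites$species_id == sp, ]
    if (nrow(st) != 1L) stopf("site counts missing for species '%s'", sp)
    for (env in envs) {
      sel <- snvs[snvs$species_id == sp & snvs$environment == env, ]
      samp_ids <- metadata$sample_id[metadata$environment == env]
      samp_ids <- intersect(samp_ids, depths$sample_id[depths$species_id == sp])
      if (nrow(sel) == 0L && length(samp_ids) == 0L) next
      n_syn <- sum(sel$snv_class == "synonymous", na.rm = TRUE)
      n_non <- sum(sel$snv_class == "nonsynonymous", na.rm = TRUE)
      n_int <- sum(sel$snv_class == "intergenic", na.rm = TRUE)

      dep <- depths[depths$species_id == sp & depths$sample_id %in% samp_ids, ]
      ratios <- c(); n_excl <- 0L
      pooled_ka <- 0; pooled_ks <- 0
      for (s in samp_ids) {
        d <- dep$mean_depth[dep$sample_id == s]
        if (length(d) != 1L || d <= 0) next
        ss <- sel[sel$sample_id == s, ]
        ka_p <- sum(ss$snv_class == "nonsynonymous", na.rm = TRUE) /
          (d * st$nonsyn_sites)
        ks_p <- sum(ss$snv_class == "synonymous", na.rm = TRUE) /
          (d * st$syn_sites)
        pooled_ka <- pooled_ka + ka_p
        pooled_ks <- pooled_ks + ks_p
        if (ks_p > 0) ratios <- c(ratios, ka_p / ks_p) else n_excl <- n_excl + 1L
      }
      ka_ks <- if (method == "per_sample") {
        if (length(ratios) > 0L) mean(ratios) else NA_real_
      } else {
        if (pooled_ks > 0) pooled_ka / pooled_ks else NA_real_
      }
      out[[length(out) + 1L]] <- data.frame(
        species_id = sp, environment = env,
        n_syn = n_syn, n_nonsyn = n_non, n_intergenic = n_int,
        syn_sites = st$syn_sites, nonsyn_sites = st$nonsyn_sites,
        ka_ks = ka_ks,
        raw_ratio = if (n_syn > 0) n_non / n_syn else NA_real_,
        n_samples = length(samp_ids), n_excluded = n_excl,
        selection = if (is.na(ka_ks)) NA_character_
                    else if (ka_ks < 1) "negative"
                    else if (ka_ks > 1) "positive" else "neutral",
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(species_id = character(), environment = character(),
                      n_syn = integer(), n_nonsyn = integer(),
                      n_intergenic = integer(), syn_sites = numeric(),
                      nonsyn_sites = numeric(), ka_ks = numeric(),
                      raw_ratio = numeric(), n_samples = integer(),
                      n_excluded = integer(), selection = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Selection pressure per COG functional category
#'
#' The site-normalized pN/pS statistic restricted to genes of each COG
#' letter, on counts pooled over samples. Categories with fewer than
#' `min_snvs` SNVs, or with zero synonymous SNVs, are reported as `NA`.
#'
#' @param snvs Annotated SNVs with `snv_class`, `gene_id`, `cog`.
#' @param sites_by_gene Per-gene site counts (`count_sites(bin, by_gene = TRUE)`).
#' @param gene_cogs Data frame `gene_id`, `cog`.
#' @param min_snvs Minimum SNVs for a defined estimate (default 10).
#' @return Data frame `cog`, `n_syn`, `n_nonsyn`, `ka_ks`.
#' @export
cog_selection <- function(snvs, sites_by_gene, gene_cogs, min_snvs = 10L) {
  sites_by_gene$cog <- gene_cogs$cog[match(sites_by_gene$gene_id, gene_cogs$gene_id)]
  snvs <- snvs[!is.na(snvs$cog) & snvs$snv_class %in%
                 c("synonymous", "nonsynonymous"), , drop = FALSE]
  cogs <- sort(unique(snvs$cog))
  out <- lapply(cogs, function(cg) {
    sel <- snvs[snvs$cog == cg, ]
    st <- sites_by_gene[!is.na(sites_by_gene$cog) & sites_by_gene$cog == cg, ]
    n_syn <- sum(sel$snv_class == "synonymous")
    n_non <- sum(sel$snv_class == "nonsynonymous")
    ka_ks <- if (nrow(sel) < min_snvs || n_syn == 0L || sum(st$syn_sites) == 0) {
      NA_real_
    } else {
      (n_non / sum(st$nonsyn_sites)) / (n_syn / sum(st$syn_sites))
    }
    data.frame(cog = cg, n_syn = n_syn, n_nonsyn = n_non, ka_ks = ka_ks,
               stringsAsFactors = FALSE)
  })
  if (length(out) == 0L) {
    return(data.frame(cog = character(), n_syn = integer(),
                      n_nonsyn = integer(), ka_ks = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
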