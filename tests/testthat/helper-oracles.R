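# Independent oracles for dual-route testing. Everything here is written
# from first principles (plain R, no calls into skincat internals) so that
# a bug in the package cannot hide in both routes.

# ---- genetic code ----------------------------------------------------------
# Translation table 11 (bacterial); its codon -> amino-acid map equals the
# standard table, written out in TCAG order.
ORACLE_TCAG <- c("T", "C", "A", "G")
ORACLE_CODE <- local({
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1L]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(ORACLE_TCAG, ORACLE_TCAG, paste0))),
    ORACLE_TCAG, paste0
  )))
  stats::setNames(aa, codons)
})

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1L]]), collapse = "")
}

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  paste(unname(ORACLE_CODE[codons]), collapse = "")
}

# Classify a substitution by retranslating the whole mutated gene product:
# no codon arithmetic at all. Assumes gene lengths are multiples of 3 and
# pure ACGT content (which the test genomes guarantee).
oracle_classify_snv <- function(bin, contig, pos, alt) {
  g <- bin$genes
  hit <- which(g$contig == contig & g$start <= pos & g$end >= pos)
  if (length(hit) == 0L) return("intergenic")
  g <- g[hit[1L], ]
  seq_ref <- bin$contigs[[contig]]
  seq_alt <- seq_ref
  substr(seq_alt, pos, pos) <- alt
  cds_ref <- substr(seq_ref, g$start, g$end)
  cds_alt <- substr(seq_alt, g$start, g$end)
  if (g$strand == "-") {
    cds_ref <- oracle_revcomp(cds_ref)
    cds_alt <- oracle_revcomp(cds_alt)
  }
  if (identical(oracle_translate(cds_ref), oracle_translate(cds_alt))) {
    "synonymous"
  } else {
    "nonsynonymous"
  }
}

# Nei-Gojobori site counts by brute force over every complete codon.
oracle_ng_sites <- function(bin) {
  syn <- 0
  non <- 0
  for (i in seq_len(nrow(bin$genes))) {
    g <- bin$genes[i, ]
    cds <- substr(bin$contigs[[g$contig]], g$start, g$end)
    if (g$strand == "-") cds <- oracle_revcomp(cds)
    nc <- nchar(cds) %/% 3L
    for (ci in seq_len(nc)) {
      codon <- substr(cds, 3L * ci - 2L, 3L * ci)
      aa <- ORACLE_CODE[[codon]]
      for (w in 1:3) {
        ref <- substr(codon, w, w)
        for (b in setdiff(c("A", "C", "G", "T"), ref)) {
          mut <- codon
          substr(mut, w, w) <- b
          if (identical(ORACLE_CODE[[mut]], aa)) syn <- syn + 1 / 3
          else non <- non + 1 / 3
        }
      }
    }
  }
  c(syn_sites = syn, nonsyn_sites = non)
}

# ---- affine-gap local alignment (Gotoh) ------------------------------------
# Convention matched to Biostrings::pairwiseAlignment: a gap of length L
# costs gapOpening + L * gapExtension. Returns the optimal local score plus
# identity/coverage derived from a full traceback.
oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

oracle_dna_submat <- local({
  m <- matrix(-3, 4L, 4L, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(m) <- 2
  m
})

oracle_local_align <- function(query, subject, submat, go, ge) {
  q <- strsplit(query, "")[[1L]]
  s <- strsplit(subject, "")[[1L]]
  n <- length(q); m <- length(s)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L); M[1L, ] <- 0; M[, 1L] <- 0
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in subject (consumes query)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in query (consumes subject)
  PM <- matrix(0L, n + 1L, m + 1L)   # predecessor state of M: 0 start 1 M 2 X 3 Y
  PX <- matrix(0L, n + 1L, m + 1L)
  PY <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      sub <- submat[q[i - 1L], s[j - 1L]]
      cand <- c(0, M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      w <- which.max(cand)
      M[i, j] <- cand[w] + sub
      PM[i, j] <- w - 1L
      cand <- c(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge,
                Y[i - 1L, j] - go - ge)
      w <- which.max(cand)
      X[i, j] <- cand[w]
      PX[i, j] <- w
      cand <- c(M[i, j - 1L] - go - ge, X[i, j - 1L] - go - ge,
                Y[i, j - 1L] - ge)
      w <- which.max(cand)
      Y[i, j] <- cand[w]
      PY[i, j] <- w
    }
  }
  best <- which(M == max(M), arr.ind = TRUE)[1L, ]
  score <- max(M, 0)
  if (score <= 0) {
    return(list(score = 0, identity = NA_real_, n_columns = 0L,
                query_span = 0L, subject_span = 0L))
  }
  # traceback from the best M cell
  i <- best[1L]; j <- best[2L]; state <- 1L
  matches <- 0L; cols <- 0L
  qe <- i - 1L; se <- j - 1L
  repeat {
    cols <- cols + 1L
    if (state == 1L) {
      if (q[i - 1L] == s[j - 1L]) matches <- matches + 1L
      nxt <- PM[i, j]
      i <- i - 1L; j <- j - 1L
      if (nxt == 0L) break
      state <- nxt
    } else if (state == 2L) {
      nxt <- PX[i, j]
      i <- i - 1L
      state <- nxt
    } else {
      nxt <- PY[i, j]
      j <- j - 1L
      state <- nxt
    }
  }
  list(score = score, identity = matches / cols, n_columns = cols,
       query_start = i, query_end = qe,
       subject_start = j, subject_end = se,
       query_span = qe - i + 1L, subject_span = se - j + 1L)
}

oracle_local_dna <- function(query, subject) {
  oracle_local_align(query, subject, oracle_dna_submat, 5, 2)
}

oracle_local_protein <- function(query, subject) {
  oracle_local_align(query, subject, oracle_blosum62, 11, 1)
}

# Greedy protein clustering by the published rule, using the oracle aligner.
oracle_cluster_proteins <- function(proteins, min_id = 0.5, min_cov = 0.9) {
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  reps <- character(0)
  assign <- character(length(proteins))
  for (i in seq_along(proteins)) {
    hit <- NA_character_
    for (r in reps) {
      aln <- oracle_local_protein(proteins[[i]], proteins[[r]])
      if (aln$score <= 0) next
      short <- min(nchar(proteins[[i]]), nchar(proteins[[r]]))
      span <- if (nchar(proteins[[i]]) <= nchar(proteins[[r]])) {
        aln$query_span
      } else {
        aln$subject_span
      }
      if (aln$identity >= min_id && span / short >= min_cov) {
        hit <- r
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, names(proteins)[i])
      hit <- names(proteins)[i]
    }
    assign[i] <- hit
  }
  stats::setNames(assign, names(proteins))
}

# ---- random sequences and mutation (test-local, seed-controlled) -----------
test_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_random_gene <- function(n_codons) {
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

test_mutate <- function(seq, n_sub) {
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample.int(length(chars), n_sub)
  chars[pos] <- vapply(chars[pos], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1L))
  paste(chars, collapse = "")
}

test_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

# A minimal one-gene genome for HGT and SNV scenarios: gene (multiple of 3)
# embedded between random flanks.
make_test_gene_bin <- function(id, gene_seq, taxon, strand = "+",
                               flank = 700L, cog = "L") {
  left <- test_random_dna(flank)
  right <- test_random_dna(flank)
  placed <- if (strand == "-") oracle_revcomp(gene_seq) else gene_seq
  contig <- paste0(left, placed, right)
  genes <- data.frame(
    gene_id = paste0(id, "_g1"), contig = paste0(id, "_c1"),
    start = flank + 1L, end = flank + nchar(gene_seq), strand = strand,
    marker_id = NA_character_, ko = "K00001", cog = cog,
    stringsAsFactors = FALSE
  )
  genome_bin(id, stats::setNames(contig, paste0(id, "_c1")), genes,
             taxon = taxon, source_sample = "test")
}

# ---- KEGG module expression trees ------------------------------------------
# Random boolean trees are generated FIRST, then serialized to the grammar
# and evaluated independently of the parser.
oracle_random_module <- function(ko_pool, max_depth = 3L) {
  new_node <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.4) {
      return(list(op = "ko", ko = sample(ko_pool, 1L)))
    }
    op <- sample(c("or", "plus", "space"), 1L)
    k <- sample(2:3, 1L)
    list(op = op, args = lapply(seq_len(k), function(i) new_node(depth + 1L)))
  }
  n_steps <- sample(1:4, 1L)
  steps <- lapply(seq_len(n_steps), function(i) new_node(1L))
  has_optional <- stats::runif(1) < 0.3
  list(steps = steps, optional = has_optional)
}

oracle_serialize_module <- function(module) {
  ser <- function(node) {
    if (node$op == "ko") return(node$ko)
    parts <- vapply(node$args, function(a) {
      s <- ser(a)
      if (a$op == "ko") s else paste0("(", s, ")")
    }, character(1L))
    switch(node$op,
           or = paste(parts, collapse = ","),
           plus = paste(parts, collapse = "+"),
           space = paste0("(", paste(parts, collapse = " "), ")"))
  }
  txt <- vapply(module$steps, ser, character(1L))
  if (module$optional) txt <- c(txt, "-K99999")
  paste(txt, collapse = " ")
}

oracle_eval_module <- function(module, ko_set) {
  ev <- function(node) {
    switch(node$op,
           ko = node$ko %in% ko_set,
           or = any(vapply(node$args, ev, logical(1L))),
           plus = all(vapply(node$args, ev, logical(1L))),
           space = all(vapply(node$args, ev, logical(1L))))
  }
  mean(vapply(module$steps, ev, logical(1L)))
}

# Spearman correlation without extra dependencies.
test_spearman <- function(a, b) stats::cor(a, b, method = "spearman")
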