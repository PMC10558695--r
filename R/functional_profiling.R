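# Nonredundant protein families by greedy incremental clustering, family
# assignment of query proteins, and KEGG metabolic-module completeness.

# Identity and shorter-sequence coverage of a protein pair via seeded local
# alignment; NULL when no seed is shared.
protein_pair_stats <- function(p, q) {
  aln <- align_pair(p, q, mode = "local", alphabet = "protein")
  if (is.null(aln)) return(NULL)
  short <- min(nchar(p), nchar(q))
  span_p <- aln$query_end - aln$query_start + 1L
  span_q <- aln$subject_end - aln$subject_start + 1L
  cov_short <- (if (nchar(p) <= nchar(q)) span_p else span_q) / short
  list(identity = aln$identity, coverage_short = cov_short,
       query_coverage = aln$query_coverage, score = aln$score)
}

#' Greedy incremental protein-family clustering
#'
#' Proteins are sorted by descending length (ties by id); each protein
#' joins the first existing family whose representative it matches at
#' `min_id` identity and `min_cov` coverage of the shorter sequence, and
#' otherwise founds a new family. Deterministic and independent of input
#' record order.
#'
#' @param proteins Named character vector of protein sequences.
#' @param min_id Minimum identity (default 0.5).
#' @param min_cov Minimum coverage of the shorter sequence (default 0.9).
#' @return Data frame `family_id`, `protein_id`, `is_representative`.
#' @export
cluster_proteins <- function(proteins, min_id = 0.5, min_cov = 0.9) {
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stopf("proteins must be uniquely named")
  }
  ord <- order(-nchar(proteins), names(proteins))
  proteins <- proteins[ord]
  reps <- character(0)          # representative protein ids, in founding order
  assign <- character(length(proteins))
  for (i in seq_along(proteins)) {
    hit <- NA_character_
    for (r in reps) {
      st <- protein_pair_stats(proteins[[i]], proteins[[r]])
      if (!is.null(st) && st$identity >= min_id && st$coverage_short >= min_cov) {
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
  fam_id <- setNames(sprintf("NPF%05d", seq_along(reps)), reps)
  data.frame(
    family_id = unname(fam_id[assign]),
    protein_id = names(proteins),
    is_representative = names(proteins) == assign,
    stringsAsFactors = FALSE
  )
}

#' Assign query proteins to existing families
#'
#' Each query goes to the best-scoring family representative whose
#' alignment covers at least `min_aln_cov` of the query and scores at
#' least `score_threshold`; ties break toward the smaller family id. The
#' default score threshold was calibrated so that random length-300
#' protein pairs exceed it less than 1e-4 of the time, standing in for a
#' BLAST E-value cutoff.
#'
#' @param queries Named character vector of query proteins.
#' @param families Output of [cluster_proteins()].
#' @param representatives Named character vector of representative protein
#'   sequences (ids as in `families$protein_id`).
#' @param min_aln_cov Minimum query coverage (default 0.30).
#' @param score_threshold Minimum alignment score (default 55).
#' @return Data frame `protein_id`, `family_id` (`NA` when unassigned),
#'   `score`, `identity`.
#' @export
assign_to_families <- function(queries, families, representatives,
                               min_aln_cov = 0.30, score_threshold = 55) {
  rep_rows <- families[families$is_representative, ]
  fam_of <- setNames(rep_rows$family_id, rep_rows$protein_id)
  rep_ids <- names(fam_of)[order(fam_of)]
  missing_seq <- setdiff(rep_ids, names(representatives))
  if (length(missing_seq) > 0L) {
    stopf("missing representative sequence(s): %s",
          paste(head(missing_seq, 3L), collapse = ", "))
  }
  out <- lapply(names(queries), function(qid) {
    best <- NULL
    for (r in rep_ids) {
      aln <- align_pair(queries[[qid]], representatives[[r]], mode = "local",
                        alphabet = "protein")
      if (is.null(aln)) next
      if (aln$query_coverage < min_aln_cov || aln$score < score_threshold) next
      if (is.null(best) || aln$score > best$score) {
        best <- list(fam = unname(fam_of[r]), score = aln$score,
                     identity = aln$identity)
      }
    }
    data.frame(
      protein_id = qid,
      family_id = if (is.null(best)) NA_character_ else best$fam,
      score = if (is.null(best)) NA_real_ else best$score,
      identity = if (is.null(best)) NA_real_ else best$identity,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

# ---- KEGG module definitions ------------------------------------------------
#
# Grammar (the de facto KEGG MODULE subset): space separates ordered steps
# (AND, lowest precedence), comma separates alternatives (OR), '+' joins
# complex subunits (AND, highest precedence), parentheses group, and
# "-K…" marks optional components (ignored).

#' Parse a KEGG module definition
#'
#' @param definition Definition string, e.g. `"K00001 (K00002,K00003+K00004)"`.
#' @return An object of class `"kegg_module"` holding the parsed top-level
#'   steps.
#' @export
parse_module_def <- function(definition) {
  if (!is.character(definition) || length(definition) != 1L ||
      is.na(definition) || !nzchar(trimws(definition))) {
    stopf("module definition must be a non-empty string")
  }
  steps <- split_top_level(definition, " ")
  parsed <- lapply(steps, parse_expr, context = definition)
  parsed <- parsed[!vapply(parsed, is.null, logical(1L))]
  if (length(parsed) == 0L) {
    stopf("module definition contains no required component")
  }
  structure(list(definition = definition, steps = parsed),
            class = "kegg_module")
}

# Split `s` on `sep` at parenthesis depth 0, dropping empty chunks.
split_top_level <- function(s, sep) {
  chars <- strsplit(s, "")[[1L]]
  depth <- 0L
  out <- character(0)
  cur <- ""
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("unbalanced ')' at position %d in '%s'", i, s)
    }
    if (ch == sep && depth == 0L) {
      out <- c(out, cur)
      cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
  }
  if (depth != 0L) stopf("unbalanced '(' in '%s'", s)
  out <- c(out, cur)
  out[nzchar(trimws(out))]
}

# Recursive descent over one step: comma (OR) over plus (AND) over atoms.
# Returns a nested list, or NULL for optional-only content.
parse_expr <- function(s, context) {
  s <- trimws(s)
  alts <- split_top_level(s, ",")
  if (length(alts) > 1L) {
    kids <- lapply(alts, parse_expr, context = context)
    kids <- kids[!vapply(kids, is.null, logical(1L))]
    if (length(kids) == 0L) return(NULL)
    return(list(op = "or", args = kids))
  }
  parts <- split_top_level(s, "+")
  if (length(parts) > 1L) {
    kids <- lapply(parts, parse_expr, context = context)
    kids <- kids[!vapply(kids, is.null, logical(1L))]
    if (length(kids) == 0L) return(NULL)
    return(list(op = "and", args = kids))
  }
  if (startsWith(s, "(") && endsWith(s, ")")) {
    inner <- substr(s, 2L, nchar(s) - 1L)
    steps <- split_top_level(inner, " ")
    if (length(steps) > 1L) {
      kids <- lapply(steps, parse_expr, context = context)
      kids <- kids[!vapply(kids, is.null, logical(1L))]
      if (length(kids) == 0L) return(NULL)
      return(list(op = "and", args = kids))
    }
    return(parse_expr(inner, context))
  }
  if (startsWith(s, "-")) return(NULL)   # optional component: ignored
  if (!grepl("^K\\d{5}$", s)) {
    pos <- regexpr(s, context, fixed = TRUE)[1L]
    stopf("unparseable token '%s' at position %d in module definition", s,
          max(pos, 1L))
  }
  list(op = "ko", ko = s)
}

eval_expr <- function(node, ko_set) {
  switch(node$op,
         ko = node$ko %in% ko_set,
         or = any(vapply(node$args, eval_expr, logical(1L), ko_set = ko_set)),
         and = all(vapply(node$args, eval_expr, logical(1L), ko_set = ko_set)))
}

#' KEGG module completeness for a KO set
#'
#' Completeness is the fraction of top-level steps whose boolean
#' expression is satisfied by `ko_set` (per-step granularity, as in
#' module-completeness heatmaps: 1 = all enzymes present, 0 = none).
#'
#' @param ko_set Character vector of KO ids present.
#' @param module A `kegg_module` or a definition string.
#' @return Fraction in \[0, 1].
#' @export
module_completeness <- function(ko_set, module) {
  if (is.character(module)) module <- parse_module_def(module)
  stopifnot(inherits(module, "kegg_module"))
  sat <- vapply(module$steps, eval_expr, logical(1L), ko_set = ko_set)
  mean(sat)
}

#' Module completeness matrix for many genomes
#'
#' @param ko_sets Named list of KO-id vectors (one per genome).
#' @param modules Named list of definitions (strings or `kegg_module`).
#' @return Genome x module numeric matrix.
#' @export
module_completeness_matrix <- function(ko_sets, modules) {
  parsed <- lapply(modules, function(m) {
    if (is.character(m)) parse_module_def(m) else m
  })
  out <- matrix(NA_real_, length(ko_sets), length(parsed),
                dimnames = list(names(ko_sets), names(parsed)))
  for (g in names(ko_sets)) {
    for (m in names(parsed)) {
      out[g, m] <- module_completeness(ko_sets[[g]], parsed[[m]])
    }
  }
  out
}
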