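# Shared-gene networks over biosynthetic gene clusters (BGCs) and their
# connected-component subnets.

#' Construct a BGC record
#'
#' @param bgc_id Unique cluster id.
#' @param genome_id Genome carrying the cluster.
#' @param product_class Free product label (e.g. NRPS, PKS, terpene).
#' @param proteins Named character vector of the cluster's gene protein
#'   sequences (at least one).
#' @export
bgc_record <- function(bgc_id, genome_id, product_class, proteins) {
  if (length(proteins) == 0L) stopf("a BGC needs at least one gene")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stopf("BGC proteins must be uniquely named")
  }
  structure(list(bgc_id = bgc_id, genome_id = genome_id,
                 product_class = product_class, proteins = proteins),
            class = "bgc_record")
}

#' Shared proteins between two BGCs
#'
#' A query gene of `a` is shared with its best hit in `b` when the
#' alignment covers at least `min_cov` of the query (inclusive) and the
#' amino-acid identity exceeds `min_id` (strict). Each query gene pairs
#' with at most its best-scoring hit.
#'
#' @param a,b `bgc_record` objects (`a` supplies the queries).
#' @param min_cov Query-coverage floor (default 0.50, inclusive).
#' @param min_id Identity floor (default 0.50, strict).
#' @return Data frame `protein_a`, `protein_b`, `identity`, `coverage`.
#' @export
shared_proteins <- function(a, b, min_cov = 0.50, min_id = 0.50) {
  out <- list()
  for (p in names(a$proteins)) {
    best <- NULL
    for (q in names(b$proteins)) {
      aln <- align_pair(a$proteins[[p]], b$proteins[[q]], mode = "local",
                        alphabet = "protein")
      if (is.null(aln)) next
      if (is.null(best) || aln$score > best$aln$score) best <- list(q = q, aln = aln)
    }
    if (is.null(best)) next
    if (best$aln$query_coverage >= min_cov && best$aln$identity > min_id) {
      out[[length(out) + 1L]] <- data.frame(
        protein_a = p, protein_b = best$q, identity = best$aln$identity,
        coverage = best$aln$query_coverage, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      identity = numeric(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build the shared-gene BGC network
#'
#' An undirected edge connects two clusters when they share at least
#' `min_shared` genes. The query-coverage criterion is directional, so an
#' unordered protein pair counts as shared when it qualifies in either
#' direction; edge weight is the mean identity of the shared pairs.
#' Connected components are extracted with igraph.
#'
#' @param bgcs Named list of `bgc_record` (names = bgc ids), or unnamed.
#' @param min_shared Minimum shared genes per edge (default 1).
#' @param min_cov,min_id Sharing thresholds (see [shared_proteins()]).
#' @return List of class `"bgc_network"`: `nodes`, `edges` (data frame
#'   `bgc_a`, `bgc_b`, `shared_gene_count`, `mean_identity`), `membership`
#'   (named component index), `components` (list of node-id vectors).
#' @export
build_network <- function(bgcs, min_shared = 1L, min_cov = 0.50, min_id = 0.50) {
  if (is.null(names(bgcs))) {
    names(bgcs) <- vapply(bgcs, `[[`, character(1L), "bgc_id")
  }
  ids <- sort(names(bgcs))
  edges <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      ab <- shared_proteins(bgcs[[ids[i]]], bgcs[[ids[j]]], min_cov, min_id)
      ba <- shared_proteins(bgcs[[ids[j]]], bgcs[[ids[i]]], min_cov, min_id)
      pairs <- unique(rbind(
        ab[, c("protein_a", "protein_b", "identity")],
        if (nrow(ba) > 0L) {
          data.frame(protein_a = ba$protein_b, protein_b = ba$protein_a,
                     identity = ba$identity, stringsAsFactors = FALSE)
        }
      ))
      # one row per unordered protein pair
      pairs <- pairs[!duplicated(paste(pairs$protein_a, pairs$protein_b)), ,
                     drop = FALSE]
      if (nrow(pairs) >= min_shared) {
        edges[[length(edges) + 1L]] <- data.frame(
          bgc_a = ids[i], bgc_b = ids[j],
          shared_gene_count = nrow(pairs),
          mean_identity = mean(pairs$identity), stringsAsFactors = FALSE
        )
      }
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(bgc_a = character(), bgc_b = character(),
               shared_gene_count = integer(), mean_identity = numeric(),
               stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("bgc_a", "bgc_b")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[ids]
  structure(list(
    nodes = ids, edges = edges, membership = membership,
    components = split(ids, membership)
  ), class = "bgc_network")
}

#' @export
print.bgc_network <- function(x, ...) {
  cat(sprintf("<bgc_network> %d node(s), %d edge(s), %d component(s)\n",
              length(x$nodes), nrow(x$edges), length(x$components)))
  invisible(x)
}

#' Summarize the network's connected-component subnets
#'
#' @param network A `bgc_network`.
#' @param bgcs The `bgc_record` list the network was built from.
#' @param genome_taxa Optional named vector genome id -> taxon label, used
#'   to report the taxa spanned by each component.
#' @return Data frame `component`, `size`, `product_classes`, `genomes`,
#'   `taxa`.
#' @export
subnet_summary <- function(network, bgcs, genome_taxa = NULL) {
  if (is.null(names(bgcs))) {
    names(bgcs) <- vapply(bgcs, `[[`, character(1L), "bgc_id")
  }
  if (length(network$components) == 0L) {
    return(data.frame(component = integer(), size = integer(),
                      product_classes = character(), genomes = character(),
                      taxa = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_along(network$components), function(k) {
    members <- network$components[[k]]
    classes <- sort(unique(vapply(bgcs[members], `[[`, character(1L),
                                  "product_class")))
    genomes <- sort(unique(vapply(bgcs[members], `[[`, character(1L),
                                  "genome_id")))
    taxa <- if (is.null(genome_taxa)) NA_character_ else
      paste(sort(unique(unname(genome_taxa[genomes]))), collapse = ";")
    data.frame(component = k, size = length(members),
               product_classes = paste(classes, collapse = ";"),
               genomes = paste(genomes, collapse = ";"), taxa = taxa,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
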