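# End-to-end orchestration: simulate -> qc -> derep -> abundance ->
# function -> snv -> hgt -> bgcnet, with a YAML-able config, a single
# reproducibility seed, and a checksummed run manifest.

STAGES <- c("simulate", "qc", "derep", "abundance", "functional", "snv",
            "hgt", "bgcnet")
STAGE_DEPS <- list(
  simulate = character(0), qc = "simulate", derep = "qc",
  abundance = "derep", functional = "derep", snv = "derep", hgt = "derep",
  bgcnet = "simulate"
)

# A compact built-in module set for the functional stage; definitions use
# the KEGG grammar (space = step, comma = OR, + = complex).
BUILTIN_MODULES <- c(
  M0001 = "K00001 K00002 (K00003,K00004)",
  M0002 = "K00010+K00011 K00012",
  M0003 = "(K00020,K00021) (K00022,K00023) K00024",
  M0004 = "K00030 K00031 K00032 K00033"
)

#' Default pipeline configuration
#'
#' All analysis thresholds default to the catalog-construction values:
#' quality tiers 0.90/0.05 and 0.50/0.10, species clustering 0.95 ANI and
#' 0.30 alignment fraction, SNV filters of 5 reads / 0.05 frequency / FDR
#' 1e-6, HGT recency 0.01, protein families 0.5/0.9, family assignment
#' coverage 0.30, BGC sharing 0.5/0.5. Simulation sizes are chosen for a
#' desk-scale end-to-end run.
#'
#' @param seed Master seed (default 1).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = as.list(setNames(rep(TRUE, length(STAGES)), STAGES)),
    simulate = list(
      n_species = 4L, genome_length = 30000L, n_genes_per_genome = 12L,
      n_contigs = 4L, n_markers = 12L, n_phyla = 2L, taxon_tree_depth = 3L,
      bins_per_species = 2L, within_ani = 0.97,
      bin_completeness = c(1.0, 0.9), bin_contamination = c(0, 0.05),
      n_samples = 4L, depth_scale = 50, noise_cv = 0.1,
      n_snvs = 300L, nonsyn_fraction = 0.35, intergenic_fraction = 0.1,
      pileup_depth = 50L, error_rate = 0.001,
      hgt_divergences = c(0.005, 0.05),
      bgc_families = 2L, bgc_clusters_per_family = 3L, bgc_genes = 4L
    ),
    derep = list(ani_threshold = 0.95, af_threshold = 0.30,
                 fragment_length = 1000L),
    abundance = list(k = 31L, containment_threshold = 0.6, n_reads = 150L,
                     read_length = 150L),
    functional = list(min_id = 0.5, min_cov = 0.9, min_aln_cov = 0.30,
                      score_threshold = 55),
    snv = list(min_depth = 5L, min_freq = 0.05, fdr = 1e-6,
               error_rate = 0.001),
    hgt = list(rank = 1L, min_identity = 0.9, recency_threshold = 0.01),
    bgcnet = list(min_shared = 1L, min_cov = 0.50, min_id = 0.50)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

validate_config <- function(config) {
  on_stages <- names(Filter(isTRUE, config$stages))
  for (st in on_stages) {
    missing_dep <- setdiff(STAGE_DEPS[[st]], on_stages)
    if (length(missing_dep) > 0L) {
      stopf("stage '%s' requires stage '%s' to be enabled", st, missing_dep[1L])
    }
  }
  for (v in c(config$derep$ani_threshold, config$derep$af_threshold,
              config$snv$min_freq, config$hgt$min_identity,
              config$bgcnet$min_id, config$bgcnet$min_cov)) {
    if (!is_fraction(v)) stopf("fractional thresholds must lie in [0, 1]")
  }
  if (is.null(config$seed)) stopf("a seed is required")
  invisible(config)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order on a synthetic
#' community with known truth, writes each stage's tables under `outdir`,
#' and returns (and writes) a manifest of parameters, seed, per-stage
#' outputs and their MD5 checksums. Rerunning with the same configuration
#' and seed reproduces byte-identical outputs.
#'
#' @param config Configuration from [default_config()] or [read_config()].
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return The manifest, invisibly; also written to
#'   `file.path(outdir, "manifest.json")`.
#' @export
run_pipeline <- function(config = default_config(), outdir, quiet = FALSE) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(seed = seed, parameters = config, stages = list())
  state <- new.env(parent = emptyenv())

  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      outputs = files,
      md5 = as.list(tools::md5sum(files))
    )
  }

  if (isTRUE(config$stages$simulate)) {
    say("stage simulate")
    sc <- config$simulate
    sim <- generate_species_set(
      n_species = sc$n_species, genome_length = sc$genome_length,
      n_genes_per_genome = sc$n_genes_per_genome,
      taxon_tree_depth = sc$taxon_tree_depth,
      seed = derive_seed(seed, "species"), n_contigs = sc$n_contigs,
      n_markers = sc$n_markers, n_phyla = sc$n_phyla
    )
    species <- sim$bins
    # derive bins: each species yields bins at within-species ANI with
    # controlled quality
    bins <- list()
    for (i in seq_along(species)) {
      sp <- species[[i]]
      for (bnum in seq_len(sc$bins_per_species)) {
        src <- if (bnum == 1L) sp else
          mutate_to_ani(sp, sc$within_ani,
                        seed = derive_seed(seed, paste0("ani", i, "_", bnum)),
                        new_id = sprintf("%s_v%d", sp$bin_id, bnum))
        comp <- sc$bin_completeness[(bnum - 1L) %% length(sc$bin_completeness) + 1L]
        cont <- sc$bin_contamination[(bnum - 1L) %% length(sc$bin_contamination) + 1L]
        b <- make_bin(src, comp, cont,
                      foreign_pool = species[setdiff(seq_along(species), i)],
                      markers = sim$markers,
                      seed = derive_seed(seed, paste0("bin", i, "_", bnum)),
                      new_id = sprintf("%s_b%d", sp$bin_id, bnum))
        bins[[b$bin_id]] <- b
      }
    }
    # plant HGTs between the first species of different phyla
    hgt_truth <- NULL
    if (length(sc$hgt_divergences) > 0L && sc$n_phyla >= 2L &&
        sc$n_species >= 2L) {
      donor <- species[[1L]]
      # recipients must sit in a different top-level group than the donor
      other_phylum <- which((seq_len(sc$n_species) - 1L) %% sc$n_phyla != 0L)
      for (h in seq_along(sc$hgt_divergences)) {
        rec_i <- other_phylum[(h - 1L) %% length(other_phylum) + 1L]
        rec_id <- paste0(species[[rec_i]]$bin_id, "_b1")
        gene <- donor$genes$gene_id[nrow(donor$genes) - (h - 1L)]
        pl <- plant_hgt(donor, bins[[rec_id]], gene,
                        divergence = sc$hgt_divergences[h],
                        seed = derive_seed(seed, paste0("hgt", h)))
        bins[[rec_id]] <- pl$recipient
        hgt_truth <- rbind(hgt_truth, pl$event)
      }
    }
    # abundances and coverage over species genomes
    ab <- with_seed(derive_seed(seed, "abund"), {
      m <- matrix(runif(sc$n_species * sc$n_samples, 0.2, 1),
                  sc$n_species, sc$n_samples,
                  dimnames = list(names(species),
                                  sprintf("s%02d", seq_len(sc$n_samples))))
      sweep(m, 2L, colSums(m), "/")
    })
    coverage <- simulate_coverage(ab, species, depth_scale = sc$depth_scale,
                                  noise_cv = sc$noise_cv,
                                  seed = derive_seed(seed, "cov"))
    # pileup on the first species genome
    pile <- simulate_pileup(
      species[[1L]], n_snvs = sc$n_snvs,
      nonsyn_fraction_target = sc$nonsyn_fraction,
      intergenic_fraction_target = sc$intergenic_fraction,
      depth = sc$pileup_depth, error_rate = sc$error_rate,
      seed = derive_seed(seed, "pileup")
    )
    bgc <- generate_bgc_set(
      n_families = sc$bgc_families,
      clusters_per_family = sc$bgc_clusters_per_family,
      genes_per_cluster = sc$bgc_genes,
      genome_ids = names(species), seed = derive_seed(seed, "bgc")
    )
    state$species <- species; state$bins <- bins; state$markers <- sim$markers
    state$truth <- simulation_truth(
      species_assignments = setNames(
        rep(names(species), each = sc$bins_per_species), names(bins)
      ),
      true_abundances = ab, planted_snvs = pile$planted,
      planted_hgts = hgt_truth, shared_bgc_genes = bgc$truth, seed = seed
    )
    state$coverage <- coverage; state$pileup <- pile$pileup; state$bgcs <- bgc$bgcs

    files <- character(0)
    for (b in bins) {
      f1 <- file.path(outdir, paste0(b$bin_id, ".fasta"))
      write_fasta(b$contigs, f1)
      f2 <- file.path(outdir, paste0(b$bin_id, ".gff3"))
      write_gff3(b, f2)
      files <- c(files, f1, f2)
    }
    files <- c(files,
               write_tsv(coverage, file.path(outdir, "coverage.tsv")),
               write_tsv(pile$pileup, file.path(outdir, "pileup.tsv")),
               write_tsv(pile$planted, file.path(outdir, "planted_snvs.tsv")))
    jsonlite::write_json(
      list(species_assignments = as.list(state$truth$species_assignments),
           true_abundances = ab, seed = seed),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
    files <- c(files, file.path(outdir, "truth.json"))
    record("simulate", files)
  }

  if (isTRUE(config$stages$qc)) {
    say("stage qc")
    state$bins <- lapply(state$bins, estimate_quality, markers = state$markers)
    qc <- quality_report(state$bins)
    record("qc", write_tsv(qc, file.path(outdir, "qc.tsv")))
  }

  if (isTRUE(config$stages$derep)) {
    say("stage derep")
    dc <- config$derep
    cl <- cluster_genomes(state$bins, ani_threshold = dc$ani_threshold,
                          af_threshold = dc$af_threshold,
                          fragment_length = dc$fragment_length)
    state$clusters <- cl
    reps <- cl$clusters$bin_id[cl$clusters$is_representative]
    state$reps <- state$bins[reps]
    files <- c(write_tsv(cl$clusters, file.path(outdir, "clusters.tsv")),
               write_tsv(cl$ani, file.path(outdir, "ani.tsv")))
    rep_fa <- file.path(outdir, "representatives.fasta")
    write_fasta(unlist(lapply(state$reps, `[[`, "contigs")), rep_fa)
    record("derep", c(files, rep_fa))
  }

  if (isTRUE(config$stages$abundance)) {
    say("stage abundance")
    ac <- config$abundance
    norm <- normalize_depths(state$coverage)
    species_map <- do.call(rbind, lapply(state$species, function(b) {
      data.frame(contig_id = names(b$contigs), species_id = b$bin_id,
                 stringsAsFactors = FALSE)
    }))
    prof <- species_abundance(norm, species_map)
    reads <- sample_reads(state$species[[1L]], ac$n_reads, ac$read_length,
                          seed = derive_seed(seed, "reads"))
    rate <- classification_rate(reads, state$reps, k = ac$k,
                                threshold = ac$containment_threshold)
    state$classification_rate <- as.numeric(rate)
    prof_df <- data.frame(species_id = rownames(prof), prof,
                          check.names = FALSE, stringsAsFactors = FALSE)
    files <- c(write_tsv(prof_df, file.path(outdir, "species_abundance.tsv")),
               write_tsv(data.frame(metric = "classification_rate",
                                    value = as.numeric(rate)),
                         file.path(outdir, "classification.tsv")))
    record("abundance", files)
  }

  if (isTRUE(config$stages$functional)) {
    say("stage functional")
    fc <- config$functional
    prots <- unlist(lapply(state$reps, bin_proteins))
    names(prots) <- sub("^[^.]*\\.", "", names(prots))
    fams <- cluster_proteins(prots, min_id = fc$min_id, min_cov = fc$min_cov)
    ko_sets <- lapply(state$reps, function(b) unique(b$genes$ko))
    mods <- module_completeness_matrix(ko_sets, as.list(BUILTIN_MODULES))
    mods_df <- data.frame(genome = rownames(mods), mods, check.names = FALSE,
                          stringsAsFactors = FALSE)
    files <- c(write_tsv(fams, file.path(outdir, "protein_families.tsv")),
               write_tsv(mods_df, file.path(outdir, "module_completeness.tsv")))
    record("functional", files)
  }

  if (isTRUE(config$stages$snv)) {
    say("stage snv")
    nc <- config$snv
    ref <- state$species[[1L]]
    snvs <- call_snvs(state$pileup, min_depth = nc$min_depth,
                      min_freq = nc$min_freq, fdr = nc$fdr,
                      error_rate = nc$error_rate)
    snvs <- annotate_snvs(snvs, ref)
    # one pileup sample; assign it an environment and report the statistic
    snvs$sample_id <- "s01"
    snvs$species_id <- ref$bin_id
    sites <- count_sites(ref)
    sel <- selection_pressure(
      snvs,
      sites = data.frame(species_id = ref$bin_id,
                         syn_sites = sites[["syn_sites"]],
                         nonsyn_sites = sites[["nonsyn_sites"]]),
      metadata = data.frame(sample_id = "s01", environment = "sebaceous"),
      depths = data.frame(species_id = ref$bin_id, sample_id = "s01",
                          mean_depth = config$simulate$pileup_depth)
    )
    out_snv <- snvs
    names(out_snv)[names(out_snv) == "contig"] <- "CHROM"
    names(out_snv)[names(out_snv) == "pos"] <- "POS"
    files <- c(write_tsv(out_snv, file.path(outdir, "snvs.tsv")),
               write_tsv(sel, file.path(outdir, "selection.tsv")))
    state$snvs <- snvs; state$selection <- sel
    record("snv", files)
  }

  if (isTRUE(config$stages$hgt)) {
    say("stage hgt")
    hc <- config$hgt
    # run on representatives: contaminant contigs in lower-quality bins
    # would otherwise masquerade as cross-group transfers
    events <- detect_candidates(state$reps, rank = hc$rank,
                                min_identity = hc$min_identity)
    contrast <- cog_contrast(events)
    state$hgt_events <- events
    files <- c(write_tsv(events, file.path(outdir, "hgt_events.tsv")),
               write_tsv(contrast, file.path(outdir, "hgt_cog_contrast.tsv")))
    record("hgt", files)
  }

  if (isTRUE(config$stages$bgcnet)) {
    say("stage bgcnet")
    bc <- config$bgcnet
    net <- build_network(state$bgcs, min_shared = bc$min_shared,
                         min_cov = bc$min_cov, min_id = bc$min_id)
    taxa <- setNames(vapply(state$species, `[[`, character(1L), "taxon"),
                     names(state$species))
    summ <- subnet_summary(net, state$bgcs, genome_taxa = taxa)
    state$bgc_network <- net
    files <- c(write_tsv(net$edges, file.path(outdir, "bgc_edges.tsv")),
               write_tsv(summ, file.path(outdir, "bgc_subnets.tsv")))
    record("bgcnet", files)
  }

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(manifest, "state") <- state
  invisible(manifest)
}
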