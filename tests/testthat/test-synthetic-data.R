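# The synthetic generator: determinism, structural guarantees, and exact
# realization of planted quantities.

small_species <- function(seed, n = 2L) {
  generate_species_set(n, genome_length = 12100L, n_genes_per_genome = 5L,
                       n_contigs = 2L, n_markers = 5L, n_phyla = 2L,
                       seed = seed)
}

test_that("the generator is byte-deterministic in its seed", {
  a <- small_species(31L)
  b <- small_species(31L)
  expect_identical(a, b)
  c <- small_species(32L)
  expect_false(identical(a$bins[[1L]]$contigs, c$bins[[1L]]$contigs))
})

test_that("generated genomes have exact length, ATG starts and stop ends", {
  sim <- small_species(33L)
  for (bin in sim$bins) {
    expect_equal(genome_length(bin), 12100L)
    expect_equal(length(bin$contigs), 2L)
    for (i in seq_len(nrow(bin$genes))) {
      cds <- substr(bin$contigs[[bin$genes$contig[i]]],
                    bin$genes$start[i], bin$genes$end[i])
      if (bin$genes$strand[i] == "-") cds <- oracle_revcomp(cds)
      expect_equal(substr(cds, 1L, 3L), "ATG")
      expect_true(substr(cds, nchar(cds) - 2L, nchar(cds)) %in%
                    c("TAA", "TAG", "TGA"))
      expect_equal(nchar(cds) %% 3L, 0L)
      # no premature stop codon
      prot <- oracle_translate(cds)
      expect_false(grepl("\\*", substr(prot, 1L, nchar(prot) - 1L)))
    }
    expect_equal(sum(!is.na(bin$genes$marker_id)), 5L)
  }
  # two phyla alternate and leaf taxa are unique
  taxa <- vapply(sim$bins, `[[`, character(1L), "taxon")
  expect_equal(length(unique(taxa)), 2L)
  expect_equal(length(unique(sub(";.*", "", taxa))), 2L)
})

test_that("mutate_to_ani plants exactly the requested substitution count", {
  sim <- small_species(34L, n = 1L)
  base <- sim$bins[[1L]]
  for (ani in c(0.99, 0.95, 0.90)) {
    d <- mutate_to_ani(base, ani, seed = 7L, new_id = "mut")
    n_diff <- sum(vapply(seq_along(base$contigs), function(i) {
      test_hamming(base$contigs[[i]], d$contigs[[i]])
    }, numeric(1L)))
    expect_equal(n_diff, round((1 - ani) * genome_length(base)))
    expect_equal(unname(d$genes$start), unname(base$genes$start))
  }
  expect_error(mutate_to_ani(base, 0.5, seed = 1L), "0.8")
})

test_that("make_bin realizes completeness and contamination targets exactly", {
  sim <- generate_species_set(3, genome_length = 41100L,
                              n_genes_per_genome = 20L, n_contigs = 2L,
                              n_markers = 20L, seed = 35L)
  base <- sim$bins[[1L]]
  pool <- sim$bins[2:3]
  grid <- list(c(1, 0), c(0.9, 0.05), c(0.75, 0.1), c(0.5, 0))
  for (g in grid) {
    b <- make_bin(base, g[1L], g[2L], foreign_pool = pool,
                  markers = sim$markers, seed = 9L, new_id = "made")
    expect_equal(b$completeness, g[1L])
    expect_equal(b$contamination, g[2L])
    expect_equal(b$tier, classify_tier(g[1L], g[2L]))
  }
  expect_error(make_bin(base, 0.5, 0.05, foreign_pool = list(),
                        markers = sim$markers, seed = 1L), "foreign_pool")
})

test_that("coverage simulation is exact at zero noise and scales abundance", {
  sim <- small_species(36L)
  ab <- matrix(c(0.25, 0.75, 0.6, 0.4), 2L, 2L,
               dimnames = list(names(sim$bins), c("s1", "s2")))
  cov <- simulate_coverage(ab, sim$bins, depth_scale = 40, noise_cv = 0,
                           seed = 1L)
  for (r in seq_len(nrow(cov))) {
    sp <- sub("_c[0-9]+$", "", cov$contig_id[r])
    expect_equal(cov$depth[r], 40 * ab[sp, cov$sample_id[r]])
  }
  # noisy depths have unit-mean noise: per-sample totals stay near scale
  covn <- simulate_coverage(ab, sim$bins, depth_scale = 40, noise_cv = 0.1,
                            seed = 2L)
  expect_false(identical(cov$depth, covn$depth))
  expect_identical(covn, simulate_coverage(ab, sim$bins, depth_scale = 40,
                                           noise_cv = 0.1, seed = 2L))
})

test_that("planted pileup variants re-verify against the codon oracle", {
  sim <- small_species(37L, n = 1L)
  bin <- sim$bins[[1L]]
  res <- simulate_pileup(bin, n_snvs = 120L, nonsyn_fraction_target = 0.4,
                         intergenic_fraction_target = 0.2, depth = 30L,
                         error_rate = 0, seed = 5L)
  expect_equal(nrow(res$planted), 120L)
  expect_false(anyDuplicated(paste(res$planted$contig, res$planted$pos)) > 0L)
  for (i in seq_len(nrow(res$planted))) {
    expect_equal(
      oracle_classify_snv(bin, res$planted$contig[i], res$planted$pos[i],
                          res$planted$alt[i]),
      res$planted$class[i]
    )
  }
  # class composition is multinomial around the targets (3 sigma)
  n_non <- sum(res$planted$class == "nonsynonymous")
  expect_lt(abs(n_non - 120 * 0.4), 3 * sqrt(120 * 0.4 * 0.6) + 1)
  # pileup sites carry exactly `depth` reads and planted alts at their freq
  depth_tot <- res$pileup$A + res$pileup$C + res$pileup$G + res$pileup$T
  expect_true(all(depth_tot == 30L))
  i1 <- which(res$pileup$contig == res$planted$contig[1L] &
                res$pileup$pos == res$planted$pos[1L])
  alt_count <- res$pileup[i1, res$planted$alt[1L]]
  expect_gt(alt_count, 0L)
})

test_that("planting an HGT inserts the gene and shifts downstream models", {
  sim <- small_species(38L)
  donor <- sim$bins[[1L]]
  recipient <- sim$bins[[2L]]
  gid <- donor$genes$gene_id[3L]
  res <- plant_hgt(donor, recipient, gid, divergence = 0, seed = 4L)
  new <- res$recipient
  expect_equal(genome_length(new),
               genome_length(recipient) +
                 (donor$genes$end[3L] - donor$genes$start[3L] + 1L))
  ng <- new$genes[new$genes$gene_id == res$event$recipient_gene, ]
  expect_equal(nrow(ng), 1L)
  ins <- substr(new$contigs[[ng$contig]], ng$start, ng$end)
  di <- match(gid, donor$genes$gene_id)
  expect_equal(ins, substr(donor$contigs[[donor$genes$contig[di]]],
                           donor$genes$start[di], donor$genes$end[di]))
  # old genes still inside their contigs and sequences unchanged
  for (i in seq_len(nrow(recipient$genes))) {
    old <- recipient$genes[i, ]
    cur <- new$genes[new$genes$gene_id == old$gene_id, ]
    expect_equal(
      substr(new$contigs[[cur$contig]], cur$start, cur$end),
      substr(recipient$contigs[[old$contig]], old$start, old$end)
    )
  }
  # divergence > 0 plants the exact substitution count
  res2 <- plant_hgt(donor, recipient, gid, divergence = 0.02, seed = 4L)
  ng2 <- res2$recipient$genes[
    res2$recipient$genes$gene_id == res2$event$recipient_gene, ]
  ins2 <- substr(res2$recipient$contigs[[ng2$contig]], ng2$start, ng2$end)
  expect_equal(test_hamming(ins, ins2), round(0.02 * nchar(ins)))
})

test_that("BGC generation shares cores within families only", {
  res <- generate_bgc_set(n_families = 2L, clusters_per_family = 3L,
                          genes_per_cluster = 4L, n_shared = 1L,
                          protein_length = 120L, seed = 6L)
  expect_length(res$bgcs, 6L)
  expect_equal(nrow(res$truth), 2L * choose(3L, 2L))
  fam_of <- function(id) sub("^bgc_f([0-9]+)_.*$", "\\1", id)
  expect_true(all(fam_of(res$truth$bgc_a) == fam_of(res$truth$bgc_b)))
  # core copies within a family are ~5% diverged, cross-family unrelated
  p1 <- res$bgcs[["bgc_f1_c1"]]$proteins[[1L]]
  p2 <- res$bgcs[["bgc_f1_c2"]]$proteins[[1L]]
  q1 <- res$bgcs[["bgc_f2_c1"]]$proteins[[1L]]
  expect_lt(abs(test_hamming(p1, p2) / nchar(p1) - 0.0975), 0.06)
  expect_gt(test_hamming(p1, q1) / nchar(p1), 0.8)
})
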