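# Best-match HGT detection, recency, phylogenetic validation, COG contrast.

test_that("recency is strict at the one-percent divergence threshold", {
  expect_equal(classify_recency(c(0, 0.0099, 0.01, 0.05)),
               c("recent", "recent", "non_recent", "non_recent"))
  expect_equal(classify_recency(0.019, threshold = 0.02), "recent")
})

test_that("a community without transfers yields no candidates", {
  sim <- generate_species_set(4, genome_length = 12100L,
                              n_genes_per_genome = 5L, n_contigs = 2L,
                              n_markers = 5L, n_phyla = 2L, seed = 81L)
  ev <- detect_candidates(sim$bins)
  expect_equal(nrow(ev), 0L)
  expect_error(detect_candidates(sim$bins[1L]), "two taxon groups")
})

test_that("a planted transfer is detected with resolved orientation", {
  set.seed(82)
  G <- test_random_gene(200L)
  A1 <- make_test_gene_bin("A1", G, "p__P1;g__a1")
  A2 <- make_test_gene_bin("A2", test_mutate(G, 6L), "p__P1;g__a2")
  B1base <- make_test_gene_bin("B1", test_random_gene(200L), "p__P2;g__b1")
  B2 <- make_test_gene_bin("B2", test_random_gene(200L), "p__P2;g__b2")
  pl <- plant_hgt(A1, B1base, "A1_g1", divergence = 0.005, seed = 83L)
  bins <- list(A1 = A1, A2 = A2, B1 = pl$recipient, B2 = B2)
  ev <- detect_candidates(bins)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$gene_id, pl$event$recipient_gene)
  expect_equal(ev$donor_genome, "A1")
  expect_equal(ev$recipient_genome, "B1")
  expect_equal(ev$recency, "recent")
  # the donor group carries a second close copy, so orientation resolves
  expect_equal(ev$orientation, "resolved")
  expect_lt(ev$divergence, 0.01)
})

test_that("a vertically inherited family with in-group support is not flagged", {
  set.seed(84)
  G <- test_random_gene(200L)
  Gfar <- test_mutate(G, round(0.05 * nchar(G)))
  bins <- list(
    A1 = make_test_gene_bin("A1", G, "p__P1;g__a1"),
    A2 = make_test_gene_bin("A2", test_mutate(G, 6L), "p__P1;g__a2"),
    B1 = make_test_gene_bin("B1", Gfar, "p__P2;g__b1"),
    B2 = make_test_gene_bin("B2", test_mutate(Gfar, 6L), "p__P2;g__b2")
  )
  # every copy's best within-group hit (~0.99) beats its cross-group hit (~0.95)
  ev <- detect_candidates(bins)
  expect_equal(nrow(ev), 0L)
})

test_that("candidate detection is invariant to bin order", {
  set.seed(85)
  G <- test_random_gene(150L)
  A1 <- make_test_gene_bin("A1", G, "p__P1;g__a1")
  B1base <- make_test_gene_bin("B1", test_random_gene(150L), "p__P2;g__b1")
  C1 <- make_test_gene_bin("C1", test_random_gene(150L), "p__P1;g__c1")
  pl <- plant_hgt(A1, B1base, "A1_g1", divergence = 0.02, seed = 86L)
  bins <- list(A1 = A1, B1 = pl$recipient, C1 = C1)
  e1 <- detect_candidates(bins)
  e2 <- detect_candidates(bins[c(3L, 1L, 2L)])
  rownames(e1) <- rownames(e2) <- NULL
  expect_identical(e1, e2)
  expect_equal(e1$recency, "non_recent")
})

test_that("phylogenetic validation separates transfers from vertical descent", {
  set.seed(87)
  G <- test_random_gene(200L)
  Gp02 <- test_mutate(G, round(0.01 * nchar(G)))
  G20 <- test_mutate(G, round(0.20 * nchar(G)))
  G21 <- test_mutate(G20, round(0.01 * nchar(G)))
  # transfer scenario: every genome carries the family; B1 also received
  # A1's copy at low divergence
  A1 <- make_test_gene_bin("A1", G, "p__P1;g__a1")
  A2 <- make_test_gene_bin("A2", Gp02, "p__P1;g__a2")
  B2 <- make_test_gene_bin("B2", G20, "p__P2;g__b2")
  B1base <- make_test_gene_bin("B1", test_random_gene(200L), "p__P2;g__b1")
  pl <- plant_hgt(A1, B1base, "A1_g1", divergence = 0.005, seed = 88L)
  bins <- list(A1 = A1, A2 = A2, B1 = pl$recipient, B2 = B2)
  ev <- detect_candidates(bins)
  expect_equal(nrow(ev), 1L)
  expect_equal(validate_phylogeny(ev[1L, ], bins), "validated")
  # vertical scenario: the same family diverged along the species tree;
  # a fabricated event on it must be rejected
  C1 <- make_test_gene_bin("C1", G, "p__P1;g__c1")
  C2 <- make_test_gene_bin("C2", Gp02, "p__P1;g__c2")
  D1 <- make_test_gene_bin("D1", G20, "p__P2;g__d1")
  D2 <- make_test_gene_bin("D2", G21, "p__P2;g__d2")
  fake <- data.frame(
    gene_id = "D1_g1", donor_gene = "C1_g1", donor_genome = "C1",
    recipient_genome = "D1", donor_taxon = "p__P1", recipient_taxon = "p__P2",
    identity = 0.8, divergence = 0.2, recency = "non_recent",
    orientation = "ambiguous", cog = "L", stringsAsFactors = FALSE
  )
  vbins <- list(C1 = C1, C2 = C2, D1 = D1, D2 = D2)
  expect_equal(validate_phylogeny(fake, vbins), "rejected")
  # fewer than four genomes: the comparison is degenerate
  expect_equal(validate_phylogeny(fake, vbins[1:3]), "unvalidated")
})

test_that("COG contrast flags categories enriched among recent events", {
  mk <- function(n, recency, cog) {
    data.frame(gene_id = sprintf("g%d", seq_len(n)), recency = recency,
               cog = cog, stringsAsFactors = FALSE)
  }
  events <- rbind(
    mk(12L, "recent", "L"), mk(1L, "non_recent", "L"),
    mk(2L, "recent", "K"), mk(12L, "non_recent", "K"),
    mk(5L, "recent", "E"), mk(5L, "non_recent", "E")
  )
  res <- cog_contrast(events)
  expect_setequal(res$cog, c("L", "K", "E"))
  expect_equal(res$n_recent[res$cog == "L"], 12L)
  # L is recent-enriched, K depleted; both rank above the balanced E
  expect_true(res$q_value[res$cog == "E"] == max(res$q_value))
  expect_gt(res$odds_ratio[res$cog == "L"], 1)
  expect_lt(res$odds_ratio[res$cog == "K"], 1)
  # q-values are BH-consistent with the Fisher p-values
  expect_equal(res$q_value, p.adjust(res$p_value, method = "BH"))
  empty <- cog_contrast(events[0L, ])
  expect_equal(nrow(empty), 0L)
})
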