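# SNV calling, codon classification, site counting, selection pressure.

test_that("calls report the majority alternative allele with exact counts", {
  pileup <- data.frame(
    contig = "c1", pos = c(10L, 20L, 30L),
    ref = c("A", "C", "G"),
    A = c(30L, 5L, 0L),
    C = c(0L, 40L, 0L),
    G = c(20L, 5L, 50L),
    T = c(0L, 0L, 0L)
  )
  snvs <- call_snvs(pileup)
  # site 10: alt G at 20/50; site 20: two alts tie at 5 -> A before G; site 30: no alt
  expect_equal(nrow(snvs), 2L)
  expect_equal(snvs$pos, c(10L, 20L))
  expect_equal(snvs$alt, c("G", "A"))
  expect_equal(snvs$alt_count, c(20, 5))
  expect_equal(snvs$depth, c(50, 50))
  expect_equal(snvs$alt_freq, c(0.4, 0.1))
})

test_that("each SNV filter excludes exactly the sites built to violate it", {
  pileup <- data.frame(
    contig = "c1", pos = 1:4, ref = "A",
    A = c(30L, 2L, 96L, 19L),
    C = c(20L, 2L, 4L, 1L),
    G = 0L, T = 0L
  )
  # pos 1 passes all filters; pos 2 fails depth (4 < 5);
  # pos 3 fails frequency (4/100 < 0.05); pos 4 fails FDR (1/20 is error-like)
  snvs <- call_snvs(pileup)
  expect_equal(snvs$pos, 1L)
  expect_true(all(snvs$depth >= 5 & snvs$alt_freq >= 0.05 &
                    snvs$q_value <= 1e-6))
})

test_that("empty or malformed pileups are handled", {
  empty <- data.frame(contig = character(), pos = integer(), ref = character(),
                      A = integer(), C = integer(), G = integer(),
                      T = integer())
  expect_equal(nrow(call_snvs(empty)), 0L)
  expect_error(call_snvs(empty[, -3L]), "lacks")
  bad <- data.frame(contig = "c1", pos = 1L, ref = "N",
                    A = 1L, C = 0L, G = 0L, T = 0L)
  expect_error(call_snvs(bad), "malformed")
})

test_that("classification matches known codon substitutions on both strands", {
  #        123456789012345678
  # gene + at 3..14: ATG GCT AGC TAA
  plus <- genome_bin("plus", c(c1 = "TTATGGCTAGCTAACC"),
                     data.frame(gene_id = "g1", contig = "c1", start = 3L,
                                end = 14L, strand = "+",
                                stringsAsFactors = FALSE))
  expect_equal(classify_snv(plus, "c1", 8L, "C"), "synonymous")     # GCT->GCC
  expect_equal(classify_snv(plus, "c1", 6L, "A"), "nonsynonymous")  # GCT->ACT
  expect_equal(classify_snv(plus, "c1", 1L, "G"), "intergenic")
  expect_equal(classify_snv(plus, "c1", 16L, "A"), "intergenic")
  # same gene placed on the minus strand
  minus <- genome_bin("minus", c(c1 = paste0("TT", oracle_revcomp("ATGGCTAGCTAA"), "CC")),
                      data.frame(gene_id = "g1", contig = "c1", start = 3L,
                                 end = 14L, strand = "-",
                                 stringsAsFactors = FALSE))
  # genomic position of the GCT wobble base: coding offset 5 -> end - 5
  expect_equal(classify_snv(minus, "c1", 14L - 5L, "G"), "synonymous")
  expect_error(classify_snv(plus, "c1", 99L, "A"), "beyond")
  expect_error(classify_snv(plus, "c2", 1L, "A"), "unknown contig")
  expect_error(classify_snv(plus, "c1", 1L, "N"), "alt")
})

test_that("classification agrees with whole-protein retranslation genome-wide", {
  set.seed(71)
  g_plus <- test_random_gene(40L)
  g_minus <- test_random_gene(40L)
  bin <- genome_bin(
    "two", c(cp = paste0(test_random_dna(30L), g_plus, test_random_dna(30L)),
             cm = paste0(test_random_dna(30L), oracle_revcomp(g_minus),
                         test_random_dna(30L))),
    data.frame(gene_id = c("gp", "gm"), contig = c("cp", "cm"),
               start = 31L, end = 30L + nchar(g_plus),
               strand = c("+", "-"), stringsAsFactors = FALSE)
  )
  for (contig in c("cp", "cm")) {
    for (pos in seq(31L, 30L + nchar(g_plus), by = 7L)) {
      ref <- substr(bin$contigs[[contig]], pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        expect_equal(classify_snv(bin, contig, pos, alt),
                     oracle_classify_snv(bin, contig, pos, alt))
      }
    }
  }
})

test_that("site counts reproduce hand-computed codon degeneracy", {
  # ATG: 0 syn; GGG: 3 of 9 syn; TGG: 0 syn; TAA: TGA and TAG are still stops
  bin <- genome_bin("h", c(c1 = paste0("AA", "ATGGGGTGGTAA", "AA")),
                    data.frame(gene_id = "g1", contig = "c1", start = 3L,
                               end = 14L, strand = "+",
                               stringsAsFactors = FALSE))
  sites <- count_sites(bin)
  expect_equal(unname(sites["syn_sites"]), 5 / 3)
  expect_equal(unname(sites["nonsyn_sites"]), 31 / 3)
  # the same gene on the minus strand counts identically
  binm <- genome_bin("hm", c(c1 = paste0("AA", oracle_revcomp("ATGGGGTGGTAA"), "AA")),
                     data.frame(gene_id = "g1", contig = "c1", start = 3L,
                                end = 14L, strand = "-",
                                stringsAsFactors = FALSE))
  expect_equal(count_sites(binm), sites)
})

test_that("site counts match the brute-force Nei-Gojobori oracle", {
  set.seed(72)
  g1 <- test_random_gene(30L)
  g2 <- test_random_gene(25L)
  bin <- genome_bin(
    "ng", c(c1 = paste0(test_random_dna(20L), g1, test_random_dna(20L),
                        oracle_revcomp(g2), test_random_dna(20L))),
    data.frame(gene_id = c("a", "b"), contig = "c1",
               start = c(21L, 41L + nchar(g1)),
               end = c(20L + nchar(g1), 40L + nchar(g1) + nchar(g2)),
               strand = c("+", "-"), stringsAsFactors = FALSE)
  )
  expect_equal(count_sites(bin), oracle_ng_sites(bin), tolerance = 1e-12)
  by_gene <- count_sites(bin, by_gene = TRUE)
  expect_equal(sum(by_gene$syn_sites), unname(oracle_ng_sites(bin)["syn_sites"]),
               tolerance = 1e-12)
  # every coding position contributes exactly three substitution outcomes
  tot <- sum(by_gene$syn_sites) + sum(by_gene$nonsyn_sites)
  expect_equal(tot, (nchar(g1) + nchar(g2)))
})

test_that("selection pressure averages per-sample site-normalized ratios", {
  snvs <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s2", "s3"),
    species_id = "sp",
    snv_class = c("synonymous", "synonymous", "nonsynonymous",
                  "synonymous", "nonsynonymous", "nonsynonymous",
                  "nonsynonymous")
  )
  sites <- data.frame(species_id = "sp", syn_sites = 100, nonsyn_sites = 300)
  metadata <- data.frame(sample_id = c("s1", "s2", "s3"),
                         environment = "dry")
  depths <- data.frame(species_id = "sp", sample_id = c("s1", "s2", "s3"),
                       mean_depth = c(10, 20, 10))
  res <- selection_pressure(snvs, sites, metadata, depths)
  # s1: (1/300)/(2/100)/... -> ka'/ks' = (1/(10*300))/(2/(10*100)) = 1/6
  # s2: (2/(20*300))/(1/(20*100)) = 2/3 ; s3 has no synonymous -> excluded
  expect_equal(res$ka_ks, mean(c(1 / 6, 2 / 3)))
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$n_samples, 3L)
  expect_equal(res$selection, "negative")
  expect_equal(res$raw_ratio, 4 / 3)
  pooled <- selection_pressure(snvs, sites, metadata, depths,
                               method = "pooled")
  ka <- 1 / 3000 + 2 / 6000 + 1 / 3000
  ks <- 2 / 1000 + 1 / 2000
  expect_equal(pooled$ka_ks, ka / ks)
  bad_md <- metadata; bad_md$environment <- "volar"
  expect_error(selection_pressure(snvs, sites, bad_md, depths),
               "unknown environment")
})

test_that("per-COG selection respects the minimum SNV count", {
  snvs <- data.frame(
    snv_class = c(rep("synonymous", 6L), rep("nonsynonymous", 6L), "synonymous"),
    gene_id = c(rep("g1", 12L), "g2"),
    cog = c(rep("L", 12L), "K")
  )
  sites <- data.frame(gene_id = c("g1", "g2"), syn_sites = c(50, 40),
                      nonsyn_sites = c(150, 120))
  cogs <- data.frame(gene_id = c("g1", "g2"), cog = c("L", "K"))
  res <- cog_selection(snvs, sites, cogs, min_snvs = 10L)
  expect_equal(res$ka_ks[res$cog == "L"], (6 / 150) / (6 / 50))
  expect_true(is.na(res$ka_ks[res$cog == "K"]))   # only one SNV
})
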