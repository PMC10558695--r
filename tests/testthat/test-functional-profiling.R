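# Protein-family clustering, family assignment, and KEGG module grammar.

random_protein_set <- function(n, len, prefix) {
  aa20 <- rownames(oracle_blosum62)[1:20]
  setNames(
    vapply(seq_len(n), function(i) {
      paste(sample(aa20, len, replace = TRUE), collapse = "")
    }, character(1L)),
    sprintf("%s%02d", prefix, seq_len(n))
  )
}

mutate_protein_test <- function(p, n_sub) {
  aa20 <- rownames(oracle_blosum62)[1:20]
  chars <- strsplit(p, "")[[1L]]
  pos <- sample.int(length(chars), n_sub)
  chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(aa20, b), 1L),
                       character(1L))
  paste(chars, collapse = "")
}

test_that("identical proteins collapse into one family with one representative", {
  prots <- setNames(rep(strrep("MKLVAND", 10L), 3L), c("pa", "pb", "pc"))
  fams <- cluster_proteins(prots)
  expect_equal(length(unique(fams$family_id)), 1L)
  expect_equal(sum(fams$is_representative), 1L)
  expect_equal(fams$protein_id[fams$is_representative], "pa")
})

test_that("greedy clustering matches the independent brute-force oracle", {
  set.seed(61)
  founders <- random_protein_set(3L, 60L, "fam")
  prots <- founders
  for (f in names(founders)) {
    for (j in 1:3) {
      prots[[sprintf("%s_m%d", f, j)]] <- mutate_protein_test(founders[[f]], 6L)
    }
  }
  fams <- cluster_proteins(prots)
  oracle <- oracle_cluster_proteins(prots)
  # identical partitions: members grouped with the same representative
  impl_part <- split(fams$protein_id, fams$family_id)
  oracle_part <- split(names(oracle), oracle)
  canon <- function(p) unname(lapply(p[order(vapply(p, min, character(1L)))], sort))
  expect_equal(canon(impl_part), canon(oracle_part))
  expect_equal(length(unique(fams$family_id)), 3L)
})

test_that("an exact substring joins its parent family via shorter-side coverage", {
  set.seed(62)
  long <- random_protein_set(1L, 120L, "L")
  prots <- c(long, setNames(substr(long[[1L]], 30L, 69L), "frag"))
  fams <- cluster_proteins(prots)
  expect_equal(length(unique(fams$family_id)), 1L)
  # but an unrelated protein founds its own family
  prots2 <- c(long, random_protein_set(1L, 40L, "R"))
  fams2 <- cluster_proteins(prots2)
  expect_equal(length(unique(fams2$family_id)), 2L)
})

test_that("clustering is independent of input record order", {
  set.seed(63)
  founders <- random_protein_set(2L, 60L, "f")
  prots <- c(founders,
             setNames(mutate_protein_test(founders[[1L]], 5L), "f01_m"),
             setNames(mutate_protein_test(founders[[2L]], 5L), "f02_m"))
  f1 <- cluster_proteins(prots)
  f2 <- cluster_proteins(prots[c(3L, 1L, 4L, 2L)])
  expect_identical(f1, f2)
})

test_that("queries are assigned to their family or left unassigned", {
  set.seed(64)
  founders <- random_protein_set(2L, 80L, "fam")
  fams <- cluster_proteins(founders)
  q_member <- setNames(mutate_protein_test(founders[[1L]], 8L), "qm")
  q_random <- random_protein_set(1L, 80L, "qr")
  res <- assign_to_families(c(q_member, q_random), fams, founders)
  fam1 <- fams$family_id[fams$protein_id == "fam01"]
  expect_equal(res$family_id[res$protein_id == "qm"], fam1)
  expect_true(is.na(res$family_id[res$protein_id == "qr01"]))
  expect_error(assign_to_families(q_member, fams, founders[2L]), "missing")
})

test_that("module completeness follows the KEGG step semantics", {
  expect_equal(module_completeness(c("K00001", "K00002"), "K00001 K00002"), 1)
  expect_equal(module_completeness("K00001", "K00001 K00002"), 0.5)
  expect_equal(module_completeness("K00002", "K00001,K00002"), 1)
  expect_equal(module_completeness("K00001", "K00001+K00002"), 0)
  expect_equal(module_completeness(c("K00001", "K00002"), "K00001+K00002"), 1)
  expect_equal(module_completeness("K00001", "K00001 -K00099"), 1)
  expect_equal(module_completeness(
    c("K00003", "K00004"), "(K00001,K00003) (K00002,K00004)"), 1)
  expect_equal(module_completeness(
    "K00001", "((K00001,K00002) K00003)"), 0)   # one step: AND inside parens
  expect_equal(module_completeness(character(0), "K00001 K00002"), 0)
})

test_that("malformed module definitions are rejected with a position", {
  expect_error(parse_module_def("K00001 (K00002"), "unbalanced")
  expect_error(parse_module_def("K00001)"), "unbalanced")
  expect_error(parse_module_def("K1"), "unparseable token")
  expect_error(parse_module_def("K00001 FOO"), "position")
  expect_error(parse_module_def("   "), "non-empty")
  expect_error(parse_module_def("-K00001"), "no required component")
})

test_that("adding KOs never decreases module completeness", {
  set.seed(65)
  pool <- sprintf("K%05d", 1:25)
  for (i in 1:40) {
    mod <- oracle_random_module(pool)
    txt <- oracle_serialize_module(mod)
    ko1 <- sample(pool, sample(0:12, 1L))
    ko2 <- union(ko1, sample(pool, sample(1:8, 1L)))
    expect_gte(module_completeness(ko2, txt), module_completeness(ko1, txt))
  }
})

test_that("the completeness matrix covers every genome-module pair", {
  mat <- module_completeness_matrix(
    list(gA = c("K00001", "K00002"), gB = "K00001"),
    list(M1 = "K00001 K00002", M2 = "K00001,K00002")
  )
  expect_equal(dim(mat), c(2L, 2L))
  expect_equal(mat["gA", "M1"], 1)
  expect_equal(mat["gB", "M1"], 0.5)
  expect_equal(mat["gB", "M2"], 1)
})
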