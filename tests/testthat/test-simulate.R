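test_that("with no indels the true alignment equals the leaf sequences", {
  cfg <- small_sim_config(indel_rate = 0)
  set.seed(3)
  pr <- sample_gene_profile(cfg, "purifying")
  rec <- simulate_gene(pr, build_symmetric_tree(8, 0.2),
                       build_codon_model(pr), cfg)
  expect_false(any(grepl("-", rec$alignment, fixed = TRUE)))
  expect_identical(rec$alignment, rec$leaf_seqs)
  expect_equal(rec$counts$insertions, 0)
  expect_equal(rec$counts$deletions, 0)
})

test_that("stripping gaps from any alignment row recovers its leaf sequence", {
  ds <- small_dataset_20()
  for (rec in ds$records) {
    expect_identical(strip_gaps(rec$alignment), rec$leaf_seqs)
    expect_equal(unique(nchar(rec$alignment)) %% 3, 0)
    expect_equal(nrow(rec$annotation), nchar(rec$alignment[[1]]) / 3)
  }
})

test_that("sequences stay in frame with no stop codons", {
  ds <- small_dataset_20()
  for (rec in ds$records) {
    for (s in rec$leaf_seqs) {
      expect_equal(nchar(s) %% 3, 0)
      expect_no_error(translate_codons(s))
      expect_false(grepl("\\*", translate_codons(s)))
    }
  }
})

test_that("per-column annotations are consistent with the profile", {
  ds <- small_dataset_20()
  for (rec in ds$records) {
    ann <- rec$annotation
    expect_equal(ann$column, seq_len(nrow(ann)) - 1L)
    expect_true(all(ann$class %in% c("S0", "S1", "S2")))
    expect_equal(unname(ann$omega),
                 unname(rec$profile$omega[match(ann$class,
                                                c("S0", "S1", "S2"))]))
  }
})

test_that("datasets are reproducible and class counts exact", {
  cfg <- small_sim_config()
  a <- simulate_dataset(cfg, 20, seed = 9)
  b <- simulate_dataset(cfg, 20, seed = 9)
  expect_identical(a$manifest, b$manifest)
  expect_identical(lapply(a$records, `[[`, "alignment"),
                   lapply(b$records, `[[`, "alignment"))
  expect_equal(sum(a$manifest$label), 10)  # 50% positive
  expect_equal(sum(a$manifest$class == "purifying"), 8)
  expect_equal(sum(a$manifest$class == "neutral"), 2)

  all_pos <- simulate_dataset(
    small_sim_config(class_mix = c(purifying = 0, neutral = 0,
                                   positive = 1)), 10, seed = 2)
  expect_true(all(all_pos$manifest$label == 1))
})

test_that("a bad class mix is rejected", {
  expect_error(sim_config(class_mix = c(purifying = 0.5, neutral = 0.2,
                                        positive = 0.5)), "sum to 1")
})

test_that("leaf codon frequencies are consistent with stationarity", {
  # root drawn from pi (equal), no indels: leaves must remain ~ pi.
  # One leaf per gene is counted so the chi-square independence
  # assumption holds (sister leaves are phylogenetically correlated).
  cfg <- sim_config(indel_rate = 0, root_length_range = c(400, 600))
  set.seed(21)
  counts <- integer(61)
  total <- 0L
  ab <- codon_alphabet()
  tree <- build_symmetric_tree(8, 0.2)
  while (total < 1e5) {
    pr <- sample_gene_profile(cfg, "purifying")
    rec <- simulate_gene(pr, tree, build_codon_model(pr), cfg)
    s <- rec$leaf_seqs[["t1"]]
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    counts <- counts + tabulate(match(cods, ab$codons), 61)
    total <- total + length(cods)
  }
  p <- suppressWarnings(stats::chisq.test(counts,
                                          p = rep(1 / 61, 61)))$p.value
  expect_gt(p, 0.001)
})

test_that("deletion lengths are geometric with mean 1/q", {
  ds <- baseline_300()
  req <- unlist(lapply(ds$records, function(r) r$events$del_requested))
  expect_gt(length(req), 1e4)
  se <- sd(req) / sqrt(length(req))
  expect_lt(abs(mean(req) - 1 / 0.35), 3 * se)
})

test_that("insertions enlarge and deletions shrink the alignment coherently", {
  cfg <- small_sim_config(indel_rate = 0.3)
  set.seed(13)
  pr <- sample_gene_profile(cfg, "positive")
  rec <- simulate_gene(pr, build_symmetric_tree(8, 0.2),
                       build_codon_model(pr), cfg)
  ann <- rec$annotation
  m <- nchar(rec$alignment[[1]]) / 3
  expect_equal(nrow(ann), m)
  # inserted columns are flagged and no column is entirely gaps
  gap_cols <- vapply(seq_len(m), function(j) {
    all(vapply(rec$alignment, function(row)
      substr(row, 3 * j - 2, 3 * j) == "---", TRUE))
  }, TRUE)
  expect_false(any(gap_cols))
  if (rec$counts$insertions > 0) expect_true(any(ann$inserted))
})
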