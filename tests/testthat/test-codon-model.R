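# Independent brute-force classification of codon pairs, used as the oracle
# against the model's rate matrices.
enumerate_pairs <- function() {
  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)[gc_map != "*"]
  out <- list()
  for (a in codons) for (b in codons) {
    if (a == b) next
    d <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (length(d) != 1) next
    pair <- sort(c(substr(a, d, d), substr(b, d, d)))
    out[[paste(a, b)]] <- list(
      i = match(a, codons), j = match(b, codons),
      transition = identical(pair, c("A", "G")) ||
        identical(pair, c("C", "T")),
      nonsyn = gc_map[[a]] != gc_map[[b]])
  }
  out
}

test_that("rates exist exactly for single-nucleotide sense changes", {
  pr <- fixed_profile()
  m <- build_codon_model(pr)
  pairs <- enumerate_pairs()
  allowed <- matrix(FALSE, 61, 61)
  for (p in pairs) allowed[p$i, p$j] <- TRUE
  for (c in 1:3) {
    Q <- m$Q[[c]]
    off <- Q; diag(off) <- 0
    expect_true(all(off[allowed] > 0))
    expect_true(all(off[!allowed] == 0))
    expect_equal(rowSums(Q), rep(0, 61), tolerance = 1e-12)
  }
  expect_equal(length(m$codons), 61)
  expect_false(any(c("TAA", "TAG", "TGA") %in% m$codons))
})

test_that("neutral parameters give identical permitted rates", {
  pr <- fixed_profile(kappa = 1, omega = c(1, 1, 1))
  m <- build_codon_model(pr)
  for (c in 1:3) {
    off <- m$Q[[c]]; diag(off) <- 0
    vals <- off[off > 0]
    expect_equal(max(vals), min(vals))
  }
})

test_that("the class mixture substitution rate is normalized to 1", {
  set.seed(44)
  cfg <- sim_config()
  for (cls in c("purifying", "positive")) {
    pr <- sample_gene_profile(cfg, cls)
    m <- build_codon_model(pr)
    rate <- sum(pr$p * vapply(1:3, function(c)
      sum(m$pi * m$exit_rates[, c]), numeric(1)))
    expect_equal(rate, 1, tolerance = 1e-12)
  }
})

test_that("kappa and omega scale rates as the model prescribes", {
  # kappa = 2, omega = 0.5 everywhere, equal frequencies:
  # rate(synonymous transition) / rate(nonsynonymous transversion) =
  # kappa / omega = 4, checked via brute-force pair classification
  pr <- fixed_profile(kappa = 2, omega = c(0.5, 0.5, 0.5))
  m <- build_codon_model(pr)
  pairs <- enumerate_pairs()
  syn_ts <- Filter(function(p) p$transition && !p$nonsyn, pairs)
  non_tv <- Filter(function(p) !p$transition && p$nonsyn, pairs)
  r1 <- vapply(syn_ts, function(p) m$Q[[1]][p$i, p$j], numeric(1))
  r2 <- vapply(non_tv, function(p) m$Q[[1]][p$i, p$j], numeric(1))
  expect_gt(length(r1), 0)
  expect_gt(length(r2), 0)
  expect_equal(diff(range(r1)), 0)   # equal frequencies: one rate per type
  expect_equal(diff(range(r2)), 0)
  expect_equal(r1[[1]] / r2[[1]], 4, tolerance = 1e-12)
})

test_that("invalid stationary frequencies are rejected", {
  pr <- fixed_profile()
  expect_error(build_codon_model(pr, rep(1 / 60, 60)), "length 61")
  expect_error(build_codon_model(pr, rep(1 / 62, 61)), "sum to 1")
  bad <- rep(1 / 61, 61); bad[1] <- -bad[1]; bad[2] <- bad[2] + 2 / 61
  expect_error(build_codon_model(pr, bad), "positive")
})
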