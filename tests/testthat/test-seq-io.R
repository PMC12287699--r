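test_that("FASTA writing and reading round-trip exactly", {
  set.seed(6)
  seqs <- strip_gaps(random_msa(8, 120))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_identical(back, seqs)
  # 60-column wrapping on write
  expect_true(all(nchar(readLines(path)) <= 60))
})

test_that("FASTA reader normalizes and validates", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acgtac", ">b", "ACGTAC"), path)
  expect_identical(read_fasta(path), c(a = "ACGTAC", b = "ACGTAC"))

  writeLines(c(">a", "ACGT", ">a", "ACGT"), path)
  expect_error(read_fasta(path), "duplicate")

  writeLines(c(">a", "ACGTAA", ">b", "ACG"), path)
  expect_error(read_fasta(path, msa = TRUE), "unequal length")

  writeLines(c(">a", "ACXT"), path)
  expect_error(read_fasta(path), "non-IUPAC")

  file.create(path2 <- withr::local_tempfile(fileext = ".fasta"))
  expect_error(read_fasta(path2), "empty")
})

test_that("codon translation follows the universal code with gap codons", {
  expect_identical(translate_codons("ATGAAA"), "MK")
  expect_identical(translate_codons("ATG---AAA"), "M-K")
  expect_error(translate_codons("ATGTAAAAA"), "stop codon")
  expect_error(translate_codons("ATGA"), "divisible by 3")
  expect_error(translate_codons("ATGA-G"), "invalid codon")
})

test_that("translation round-trips through back-translation on simulated genes", {
  ds <- small_dataset_20()
  for (rec in ds$records[1:5]) {
    aa_msa <- vapply(rec$alignment, translate_codons, "")
    back <- backtranslate_alignment(aa_msa, rec$leaf_seqs)
    expect_identical(unname(back), unname(rec$alignment))
    expect_identical(strip_gaps(back), rec$leaf_seqs)
  }
})

test_that("back-translation handles gaps and reports mismatches by taxon", {
  expect_identical(backtranslate_alignment(c(a = "M-K"), c(a = "ATGAAA")),
                   c(a = "ATG---AAA"))
  expect_identical(backtranslate_alignment(c(a = "MK"), c(a = "ATGAAA")),
                   c(a = "ATGAAA"))
  expect_error(backtranslate_alignment(c(a = "MR"), c(a = "ATGAAA")),
               "taxon 'a'.*residue 2")
})

test_that("a missing aligner executable is a clear dependency error", {
  expect_error(
    run_external_aligner("clustalo", c(a = "ATGAAA"),
                         workdir = withr::local_tempdir()),
    "optional dependency absent")
})

test_that("the mafft adapter preserves sequence content", {
  skip_if(Sys.which("mafft") == "", "mafft not on PATH")
  ds <- small_dataset_20()
  rec <- ds$records[[1]]
  msa <- run_external_aligner("mafft", rec$leaf_seqs,
                              workdir = withr::local_tempdir())
  expect_equal(strip_gaps(msa), rec$leaf_seqs, ignore_attr = TRUE)
  expect_equal(length(unique(nchar(msa))), 1)
  expect_equal(nchar(msa[[1]]) %% 3, 0)

  # identical sequences align without gaps
  dup <- rep(rec$leaf_seqs[1], 4)
  names(dup) <- paste0("t", 1:4)
  aligned <- run_external_aligner("mafft", dup,
                                  workdir = withr::local_tempdir())
  expect_false(any(grepl("-", aligned, fixed = TRUE)))
})
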