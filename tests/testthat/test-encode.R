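test_that("characters map to their fixed bit patterns", {
  ex <- encode_msa(c(t1 = "ACG", t2 = "T-N"), label = 1, gene_id = "g")
  # channels: 1 gap, 2 T, 3 G, 4 C, 5 A
  expect_equal(ex$tensor[1, 1, ], c(0, 0, 0, 0, 1))  # A
  expect_equal(ex$tensor[1, 2, ], c(0, 0, 0, 1, 0))  # C
  expect_equal(ex$tensor[1, 3, ], c(0, 0, 1, 0, 0))  # G
  expect_equal(ex$tensor[2, 1, ], c(0, 1, 0, 0, 0))  # T
  expect_equal(ex$tensor[2, 2, ], c(1, 0, 0, 0, 0))  # gap
  expect_equal(ex$tensor[2, 3, ], c(0, 0, 0, 0, 0))  # N: all-zero
  expect_equal(dim(ex$tensor)[3], 5)
})

test_that("an all-gap column is hot on the gap channel in every row", {
  msa <- c(t1 = "A-G", t2 = "C-T", t3 = "G-A")
  ex <- encode_msa(msa, 0)
  expect_equal(ex$tensor[, 2, 1], rep(1, 3))
  expect_equal(sum(ex$tensor[, 2, -1]), 0)
})

test_that("encode/decode is the identity on random MSAs", {
  set.seed(19)
  for (i in 1:100) {
    msa <- random_msa(sample(2:8, 1), 3 * sample(2:20, 1))
    ex <- encode_msa(msa, 1)
    expect_identical(decode_tensor(ex$tensor, names(msa)), msa)
  }
})

test_that("malformed inputs are encoding/decoding errors", {
  expect_error(encode_msa(c(t1 = "ACG", t2 = "AC"), 1), "unequal")
  expect_error(encode_msa(c(t1 = "ACGT"), 1), "divisible by 3")
  expect_error(encode_msa(c(t1 = "AXG"), 1), "invalid character")
  bad <- array(0, dim = c(1, 3, 5))
  bad[1, 1, c(1, 2)] <- 1
  expect_error(decode_tensor(bad), "multiple hot channels")
  # all-zero inside true length decodes to N
  ok <- array(0, dim = c(1, 3, 5))
  ok[1, 2, 5] <- 1
  expect_identical(unname(decode_tensor(ok)), "NAN")
})

test_that("batches are zero-padded to the longest example", {
  exs <- list(encode_msa(random_msa(4, 30), 0, "a"),
              encode_msa(random_msa(4, 60), 1, "b"),
              encode_msa(random_msa(4, 90), 1, "c"))
  bt <- make_batches(exs, batch_size = 3, shuffle = FALSE)
  expect_length(bt, 1)
  expect_equal(dim(bt[[1]]$tensor), c(3, 4, 90, 5))
  expect_equal(bt[[1]]$lengths, c(30, 60, 90))
  expect_equal(sum(bt[[1]]$tensor[1, , 31:90, ]), 0)
  expect_equal(sum(bt[[1]]$tensor[2, , 61:90, ]), 0)
  # real characters fill every unpadded position
  expect_equal(sum(bt[[1]]$tensor[3, , , ]), 4 * 90)
  expect_error(make_batches(list()), "empty")
})

test_that("epoch reshuffling changes batch assignment; row shuffling preserves rows", {
  set.seed(40)
  exs <- random_examples(40)
  b1 <- make_batches(exs, 8)
  b2 <- make_batches(exs, 8)
  ids <- function(b) lapply(b, `[[`, "gene_ids")
  expect_false(identical(ids(b1), ids(b2)))

  ex <- encode_msa(random_msa(8, 30), 1, "g")
  bt <- make_batches(list(ex), 1, shuffle_rows = TRUE)[[1]]
  orig <- decode_tensor(ex$tensor)
  shuf <- decode_tensor(array(bt$tensor[1, , , ], dim = c(8, 30, 5)))
  expect_setequal(unname(shuf), unname(orig))
  expect_equal(bt$labels, 1L)
})

test_that("record files round-trip and stream with bounded memory", {
  set.seed(50)
  exs <- random_examples(10)
  path <- withr::local_tempfile(fileext = ".records")
  write_records(exs, path)
  back <- read_records(path)
  expect_equal(length(back), 10)
  for (i in 1:10) {
    expect_equal(back[[i]]$tensor, exs[[i]]$tensor)
    expect_identical(back[[i]]$label, exs[[i]]$label)
    expect_identical(back[[i]]$gene_id, exs[[i]]$gene_id)
  }
  it <- record_reader(path)
  expect_equal(attr(it, "count"), 10)
  expect_equal(attr(it, "n"), 8)
  seen <- 0
  while (!is.null(it())) seen <- seen + 1
  expect_equal(seen, 10)
})

test_that("corrupt record files are format errors", {
  set.seed(51)
  exs <- random_examples(3)
  path <- withr::local_tempfile(fileext = ".records")
  write_records(exs, path)
  raw <- readBin(path, "raw", file.size(path))
  # header count mismatch: declare 4 records but provide 3
  bad <- raw
  bad[17:20] <- writeBin(4L, raw(), size = 4, endian = "little")
  path2 <- withr::local_tempfile()
  writeBin(bad, path2)
  it <- record_reader(path2)
  expect_error({ while (!is.null(it())) NULL }, "count mismatch")
  # truncated payload
  path3 <- withr::local_tempfile()
  writeBin(raw[1:(length(raw) - 10)], path3)
  it3 <- record_reader(path3)
  expect_error({ while (!is.null(it3())) NULL }, "truncated")
  # wrong magic
  path4 <- withr::local_tempfile()
  writeBin(as.raw(rev(as.integer(raw))), path4)
  expect_error(record_reader(path4), "not a record file")
})
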