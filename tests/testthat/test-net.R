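test_that("the default architecture has seven convolutional layers", {
  spec <- cnn_spec()
  expect_length(spec$filters, 7)
  model <- build_cnn(cnn_spec(filters = c(4, 4, 8), dense_width = 8))
  expect_length(model$params$conv, 3)
  expect_length(model$params$bn, 3)
  # first-layer filter spans all rows and one codon column
  expect_equal(nrow(model$params$conv[[1]]$W), 8 * 3 * 5)
})

test_that("spec invariants are enforced", {
  expect_error(cnn_spec(filters = integer(0)), "at least one")
  expect_error(cnn_spec(dropout = 1), "dropout")
  expect_error(cnn_spec(kernel_width = 2), "odd")
  expect_error(cnn_spec(pool_width = 0), "pool_width")
})

test_that("the stride-3 first layer yields one position per codon column", {
  model <- build_cnn(tiny_spec())
  x <- array(runif(8 * 30 * 5), dim = c(1, 8, 30, 5))
  cv <- selcnn:::.conv1_forward(x, model$params$conv[[1]]$W,
                                model$params$conv[[1]]$b)
  expect_equal(nrow(cv$out), 10)  # 30 nucleotide columns -> 10 codons
  expect_equal(ncol(cv$out), 4)
})

test_that("forward passes are bounded by the sigmoid range", {
  set.seed(60)
  model <- build_cnn(tiny_spec())
  for (i in 1:20) {
    ex <- encode_msa(random_msa(8, 3 * sample(5:40, 1)), 1)
    s <- predict(model, ex)
    expect_true(s >= 0 && s <= 1)
  }
})

test_that("prediction is a pure function, invariant to batch partitioning", {
  set.seed(61)
  model <- build_cnn(tiny_spec())
  exs <- random_examples(10)
  one_by_one <- vapply(exs, function(e) unname(predict(model, e)),
                       numeric(1))
  together <- unname(predict(model, exs))
  expect_equal(together, one_by_one, tolerance = 1e-12)
  # duplicated example gives identical scores
  expect_equal(unname(predict(model, list(exs[[1]], exs[[1]])))[1],
               unname(predict(model, list(exs[[1]], exs[[1]])))[2])
})

test_that("shape mismatches raise shape errors", {
  model <- build_cnn(tiny_spec())
  ex <- encode_msa(random_msa(4, 30), 1)
  expect_error(predict(model, ex), "shape error")
})

test_that("training is deterministic given a seed and rejects one-class data", {
  set.seed(62)
  exs <- random_examples(24, Ls = c(30, 45))
  spec <- tiny_spec(epochs = 2, batch_size = 8)
  m1 <- omega_cnn(exs, spec)
  m2 <- omega_cnn(exs, spec)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$params, m2$params)
  expect_true(m1$trained)

  ones <- lapply(exs, function(e) { e$label <- 1L; e })
  expect_error(omega_cnn(ones, spec), "degenerate")
})

test_that("training on a separable toy problem reduces the loss", {
  # class 1 alignments are all-A, class 0 all-T: trivially separable
  set.seed(63)
  exs <- lapply(1:40, function(i) {
    ch <- if (i %% 2) "A" else "T"
    msa <- setNames(rep(paste(rep(ch, 30), collapse = ""), 8),
                    paste0("t", 1:8))
    encode_msa(msa, i %% 2, sprintf("g%d", i))
  })
  spec <- tiny_spec(epochs = 8, batch_size = 8, dropout = 0)
  model <- omega_cnn(exs, spec)
  h <- model$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_equal(h$train_acc[nrow(h)], 1)
  scores <- predict(model, exs)
  labels <- vapply(exs, `[[`, 0L, "label")
  expect_gt(mean(scores[labels == 1]), mean(scores[labels == 0]))
})
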