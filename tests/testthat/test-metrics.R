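# brute-force Mann-Whitney concordance with half credit for ties
mw_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

test_that("thresholding is inclusive and validated", {
  expect_equal(classify(c(0.2, 0.5, 0.9)), c(0L, 1L, 1L))
  expect_equal(classify(c(0.1, 0.9), threshold = 0), c(1L, 1L))
  expect_error(classify(c(0.5), threshold = 1.5), "threshold")
  expect_error(classify(c(-0.1)), "scores")
})

test_that("positive calls decrease monotonically over a threshold sweep", {
  set.seed(70)
  scores <- runif(200)
  counts <- vapply(seq(0, 1, by = 0.01),
                   function(t) sum(classify(scores, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a perfect classifier scores 1 everywhere", {
  rep <- compute_report(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$roc_auc, 1)
  expect_equal(rep$pr_auc, 1)
})

test_that("the worked four-point example gives ROC AUC 0.75", {
  # 3 of 4 positive-negative pairs concordant
  rep <- compute_report(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(rep$roc_auc, 0.75)
  expect_equal(rep$TP + rep$TN + rep$FP + rep$FN, rep$n)
})

test_that("ROC AUC equals brute-force concordance, including ties", {
  set.seed(71)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(attr(roc_curve(scores, truth), "auc"),
                 mw_auc(scores, truth))
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  set.seed(72)
  truth <- sample(0:1, 300, replace = TRUE)
  scores <- runif(300) * 0.5 + truth * runif(300) * 0.5
  ours <- attr(roc_curve(scores, truth), "auc")
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("reversing scores reflects the ROC AUC", {
  set.seed(73)
  truth <- sample(0:1, 100, replace = TRUE)
  scores <- runif(100)
  a <- attr(roc_curve(scores, truth), "auc")
  b <- attr(roc_curve(1 - scores, truth), "auc")
  expect_equal(a, 1 - b)
})

test_that("random scores give a null AUC of one half", {
  set.seed(74)
  truth <- rep(0:1, each = 5000)
  scores <- runif(10000)
  expect_equal(attr(roc_curve(scores, truth), "auc"), 0.5,
               tolerance = 0.02)
})

test_that("confusion counts and rates respect their identities", {
  set.seed(75)
  truth <- sample(0:1, 500, replace = TRUE)
  scores <- runif(500)
  rep <- compute_report(scores, truth, threshold = 0.3)
  expect_equal(rep$TP + rep$TN + rep$FP + rep$FN, 500)
  expect_equal(rep$accuracy, (rep$TP + rep$TN) / 500)
  expect_equal(rep$tpr, rep$TP / (rep$TP + rep$FN))
  expect_equal(rep$fpr, rep$FP / (rep$FP + rep$TN))
  expect_equal(rep$recall, rep$tpr)
  rates <- c(rep$accuracy, rep$tpr, rep$fpr, rep$precision, rep$recall)
  expect_true(all(rates >= 0 & rates <= 1))
})

test_that("single-class truth signals an undefined metric", {
  expect_warning(rep <- compute_report(c(0.2, 0.8), c(1, 1)),
                 class = "selcnn_undefined_metric")
  expect_true(is.na(rep$roc_auc))
  expect_true(is.na(rep$pr_auc))
})

test_that("the PR curve starts at the highest-score precision", {
  pr <- pr_curve(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
  expect_equal(pr$recall[1], 0)
  expect_equal(pr$precision[1], pr$precision[2])
  expect_true(all(pr$recall == cummax(pr$recall)))
})

test_that("external CODEML tables are ingested as scores", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("g1", "g2"), pvalue = c(0.01, 0.7)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_codeml_results(path)
  expect_equal(tab$score, c(0.99, 0.3))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(x = 1), path2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_codeml_results(path2), "gene_id")
})
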