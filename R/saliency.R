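#' Gradient saliency map for one alignment
#'
#' Computes the derivative w of the sigmoid output Z with respect to the
#' one-hot input tensor at the given example (by backpropagation, in
#' inference mode), then reduces the `n x L x 5` gradient to an `n x L`
#' importance matrix by taking the maximum magnitude across the five
#' channels at each alignment position. The example is processed at its
#' true length, so padded positions never appear in the map.
#'
#' @param model an `omega_cnn` model.
#' @param example an `encoded_example`.
#' @param aggregate how to summarize each codon column (3 nucleotide
#'   columns x n rows) into the per-codon profile: `"max"` (default,
#'   conservative) or `"mean"`.
#' @return an object of class `saliency_map`: list with `M` (`n x L`
#'   non-negative matrix), `per_codon` (length `L/3`), `score` (the model
#'   output Z), `gene_id`, `n`, `L`.
#' @export
saliency_map <- function(model, example,
                         aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(model, "omega_cnn"),
            inherits(example, "encoded_example"))
  tensor <- array(example$tensor,
                  dim = c(1, example$n, example$L, 5))
  fw <- .net_forward(model$params, model$bn_state, model$spec, tensor,
                     training = FALSE)
  # dZ/d(pre-sigmoid) evaluated at the example; saliency is defined on Z
  d_zpre <- fw$Z * (1 - fw$Z)
  bw <- .net_backward(model$params, model$spec, fw, d_zpre,
                      want_input_grad = TRUE)
  w <- array(bw$dx, dim = c(example$n, example$L, 5))
  M <- apply(abs(w), c(1, 2), max)
  if (any(!is.finite(M)))
    stop("non-finite saliency values", call. = FALSE)
  m <- example$L %/% 3
  codon_of <- rep(seq_len(m), each = 3)
  per_codon <- vapply(seq_len(m), function(j) {
    block <- M[, codon_of == j, drop = FALSE]
    if (aggregate == "max") max(block) else mean(block)
  }, numeric(1))
  structure(list(M = M, per_codon = per_codon, score = fw$Z,
                 gene_id = example$gene_id, n = example$n, L = example$L,
                 aggregate = aggregate),
            class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("Saliency map for '%s' (%d x %d, model score %.4f)\n",
              x$gene_id, x$n, x$L, x$score))
  cat(sprintf("  per-codon aggregate: %s; top column %d (value %.3g)\n",
              x$aggregate, which.max(x$per_codon), max(x$per_codon)))
  invisible(x)
}

#' Heatmap of a saliency map
#'
#' @param x a [saliency_map()] result.
#' @param ... passed to [graphics::image()].
#' @export
plot.saliency_map <- function(x, ...) {
  graphics::image(t(x$M[rev(seq_len(x$n)), , drop = FALSE]),
                  xlab = "alignment column", ylab = "row", axes = FALSE,
                  main = sprintf("Saliency: %s", x$gene_id), ...)
  invisible(x)
}

#' Site-class enrichment of saliency
#'
#' Summarizes how saliency relates to the true site classes of a simulated
#' gene: mean per-codon saliency of positively selected (S2) columns versus
#' the rest, their ratio, and a rank-sum enrichment statistic with a
#' column-label permutation p-value. With no S2 column the enrichment is
#' reported as undefined rather than raising an error.
#'
#' @param map a [saliency_map()] result.
#' @param annotation the gene's annotation data frame (columns `column`,
#'   `class`), as produced by [simulate_gene()]; its length must match the
#'   map's codon-column count.
#' @param n_perm number of label permutations for the p-value.
#' @return list with `mean_s2`, `mean_other`, `ratio`, `rank_sum` (sum of
#'   S2 column ranks), `p_value`, `n_s2`, `n_columns`, and `undefined`.
#' @export
site_class_enrichment <- function(map, annotation, n_perm = 999) {
  stopifnot(inherits(map, "saliency_map"))
  m <- length(map$per_codon)
  if (nrow(annotation) != m)
    stop("annotation length (", nrow(annotation),
         ") does not match the map's codon columns (", m, ")",
         call. = FALSE)
  s2 <- annotation$class == "S2"
  n_s2 <- sum(s2)
  if (n_s2 == 0 || n_s2 == m) {
    return(list(mean_s2 = if (n_s2) mean(map$per_codon) else NA_real_,
                mean_other = if (n_s2) NA_real_ else mean(map$per_codon),
                ratio = NA_real_, rank_sum = NA_real_,
                p_value = NA_real_, n_s2 = n_s2, n_columns = m,
                undefined = TRUE))
  }
  s <- map$per_codon
  mean_s2 <- mean(s[s2])
  mean_other <- mean(s[!s2])
  ratio <- if (mean_other > 0) mean_s2 / mean_other else Inf
  rk <- rank(s)
  obs <- sum(rk[s2])
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    exceed <- exceed + (sum(rk[sample.int(m, n_s2)]) >= obs)
  }
  list(mean_s2 = mean_s2, mean_other = mean_other, ratio = ratio,
       rank_sum = obs, p_value = (1 + exceed) / (n_perm + 1),
       n_s2 = n_s2, n_columns = m, undefined = FALSE)
}
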