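#' Sample per-gene evolutionary parameters
#'
#' Draws one gene's parameter set from the configured distributions: kappa
#' from U(2, 3); site-class proportions p0 ~ U(0.5, 0.8) and p2 ~ U(0.01,
#' 0.1) with p1 the complement; omega0 ~ U(0.1, 0.5) and omega1 ~ U(0.5,
#' 0.9); omega2 according to the gene class (purifying U(0.9, 1), neutral
#' exactly 1, positive U(1.5, 5)); and the root length in codons from a
#' gamma(k = 4.2, theta = 85) rounded to the nearest integer and resampled
#' until it falls within [100, 600]. The binary label is 1 exactly for
#' positive-class genes.
#'
#' @param config a [sim_config()] object.
#' @param gene_class one of `"purifying"`, `"neutral"`, `"positive"`.
#' @return an object of class `gene_profile`: list with `kappa`, `omega`
#'   (length 3), `p` (length 3, sums to 1), `root_length`, `gene_class`,
#'   `label`.
#' @export
#' @examples
#' set.seed(42)
#' sample_gene_profile(sim_config(), "positive")
sample_gene_profile <- function(config, gene_class = c("purifying",
                                                       "neutral",
                                                       "positive")) {
  gene_class <- match.arg(gene_class)
  kappa <- runif(1, config$kappa_range[1], config$kappa_range[2])
  p0 <- runif(1, config$p0_range[1], config$p0_range[2])
  p2 <- runif(1, config$p2_range[1], config$p2_range[2])
  p1 <- 1 - p0 - p2
  omega0 <- runif(1, config$omega0_range[1], config$omega0_range[2])
  omega1 <- runif(1, config$omega1_range[1], config$omega1_range[2])
  o2r <- switch(gene_class,
                purifying = config$omega2_purifying,
                neutral = config$omega2_neutral,
                positive = config$omega2_positive)
  omega2 <- if (o2r[1] == o2r[2]) o2r[1] else runif(1, o2r[1], o2r[2])
  lo <- config$root_length_range[1]
  hi <- config$root_length_range[2]
  repeat {
    root_length <- round(rgamma(1, shape = config$root_length_shape,
                                scale = config$root_length_scale))
    if (root_length >= lo && root_length <= hi) break
  }
  structure(list(kappa = kappa,
                 omega = c(omega0, omega1, omega2),
                 p = c(p0, p1, p2),
                 root_length = as.integer(root_length),
                 gene_class = gene_class,
                 label = as.integer(gene_class == "positive")),
            class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  cat(sprintf("Gene profile (%s, label %d)\n", x$gene_class, x$label))
  cat(sprintf("  kappa %.3f | omega (%.3f, %.3f, %.3f) | p (%.3f, %.3f, %.3f)\n",
              x$kappa, x$omega[1], x$omega[2], x$omega[3],
              x$p[1], x$p[2], x$p[3]))
  cat(sprintf("  root length %d codons\n", x$root_length))
  invisible(x)
}
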