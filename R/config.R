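#' Simulation configuration
#'
#' Bundles every distribution bound used by the sequence-evolution simulator.
#' Defaults are the baseline study conditions: an 8-taxon symmetric tree with
#' 0.2 expected substitutions per codon site per branch, an indel rate of 0.1
#' per substitution with insertion:deletion ratio 1 and geometric codon
#' lengths (q = 0.35), gene classes mixed 40% purifying / 10% neutral / 50%
#' positive, root lengths from a truncated gamma(k = 4.2, theta = 85), kappa
#' from U(2, 3) and site-class parameters p0 ~ U(0.5, 0.8), p2 ~ U(0.01, 0.1),
#' omega0 ~ U(0.1, 0.5), omega1 ~ U(0.5, 0.9) with omega2 drawn per gene
#' class (purifying U(0.9, 1), neutral 1, positive U(1.5, 5)).
#'
#' @param n_taxa number of leaves of the symmetric tree (power of two).
#' @param divergence branch length, expected substitutions per codon site.
#' @param kappa_range range of the transition/transversion ratio.
#' @param omega0_range,omega1_range ranges of the purifying site-class dN/dS.
#' @param omega2_purifying,omega2_neutral,omega2_positive ranges of the third
#'   site class's dN/dS for each gene class.
#' @param p0_range,p2_range ranges of the S0 and S2 site-class proportions;
#'   p1 is the complement.
#' @param root_length_shape,root_length_scale gamma parameters (codons) of
#'   the root sequence length.
#' @param root_length_range inclusive truncation bounds in codons.
#' @param class_mix named proportions of purifying/neutral/positive genes.
#' @param indel_rate total indel (insertion + deletion) rate per codon site,
#'   relative to the mean-1 substitution rate.
#' @param ins_del_ratio ratio of insertion to deletion rates.
#' @param indel_geom_q success probability of the geometric indel length
#'   distribution over k >= 1 codons, P(k) = q (1-q)^(k-1).
#' @param codon_freqs stationary frequencies over the 61 sense codons, or
#'   `NULL` for equal frequencies 1/61.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(divergence = 0.5)
#' cfg$divergence
sim_config <- function(n_taxa = 8,
                       divergence = 0.2,
                       kappa_range = c(2, 3),
                       omega0_range = c(0.1, 0.5),
                       omega1_range = c(0.5, 0.9),
                       omega2_purifying = c(0.9, 1.0),
                       omega2_neutral = c(1, 1),
                       omega2_positive = c(1.5, 5),
                       p0_range = c(0.5, 0.8),
                       p2_range = c(0.01, 0.1),
                       root_length_shape = 4.2,
                       root_length_scale = 85,
                       root_length_range = c(100, 600),
                       class_mix = c(purifying = 0.4, neutral = 0.1,
                                     positive = 0.5),
                       indel_rate = 0.1,
                       ins_del_ratio = 1,
                       indel_geom_q = 0.35,
                       codon_freqs = NULL) {
  cfg <- list(n_taxa = n_taxa, divergence = divergence,
              kappa_range = kappa_range, omega0_range = omega0_range,
              omega1_range = omega1_range,
              omega2_purifying = omega2_purifying,
              omega2_neutral = omega2_neutral,
              omega2_positive = omega2_positive,
              p0_range = p0_range, p2_range = p2_range,
              root_length_shape = root_length_shape,
              root_length_scale = root_length_scale,
              root_length_range = root_length_range,
              class_mix = class_mix, indel_rate = indel_rate,
              ins_del_ratio = ins_del_ratio, indel_geom_q = indel_geom_q,
              codon_freqs = codon_freqs)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!(cfg$n_taxa %in% c(2, 4, 8, 16)))
    stop("n_taxa must be a power of two in {2, 4, 8, 16}", call. = FALSE)
  if (cfg$divergence <= 0) stop("divergence must be > 0", call. = FALSE)
  if (cfg$indel_rate < 0) stop("indel_rate must be >= 0", call. = FALSE)
  if (cfg$indel_geom_q <= 0 || cfg$indel_geom_q > 1)
    stop("indel_geom_q must lie in (0, 1]", call. = FALSE)
  mix <- cfg$class_mix
  if (is.null(names(mix)) ||
      !all(sort(names(mix)) %in% c("neutral", "positive", "purifying")))
    stop("class_mix must be named with purifying/neutral/positive",
         call. = FALSE)
  if (abs(sum(mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1", call. = FALSE)
  if (any(mix < 0)) stop("class_mix proportions must be >= 0", call. = FALSE)
  if (!is.null(cfg$codon_freqs)) {
    if (length(cfg$codon_freqs) != 61 ||
        abs(sum(cfg$codon_freqs) - 1) > 1e-9 || any(cfg$codon_freqs <= 0))
      stop("codon_freqs must be 61 positive values summing to 1",
           call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Codon-evolution simulation configuration\n")
  cat(sprintf("  tree: %d taxa, divergence %.3g subs/codon site/branch\n",
              x$n_taxa, x$divergence))
  cat(sprintf("  indels: rate %.3g per substitution, ins:del %.3g, geometric q = %.3g\n",
              x$indel_rate, x$ins_del_ratio, x$indel_geom_q))
  cat(sprintf("  gene class mix: %s\n",
              paste(sprintf("%s %.0f%%", names(x$class_mix),
                            100 * x$class_mix), collapse = ", ")))
  cat(sprintf("  root length: gamma(%.3g, %.3g) truncated to [%d, %d] codons\n",
              x$root_length_shape, x$root_length_scale,
              x$root_length_range[1], x$root_length_range[2]))
  invisible(x)
}
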