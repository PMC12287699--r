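# Sense-codon alphabet (universal genetic code) and the site-class codon
# substitution model: rates exist only between codons one nucleotide apart
# (stop codons excluded), proportional to the target frequency, multiplied
# by kappa for transitions and by the site class's omega for nonsynonymous
# changes.

.codon_env <- new.env(parent = emptyenv())

#' Sense-codon alphabet and genetic code
#'
#' The 61 sense codons of the universal genetic code (stop codons TAA, TAG
#' and TGA excluded) with their amino-acid translations.
#'
#' @return a list with `codons` (character 61), `aa` (amino acids, character
#'   61), and `stops` (the three stop codons).
#' @export
codon_alphabet <- function() {
  if (is.null(.codon_env$tab)) {
    gc_map <- Biostrings::GENETIC_CODE
    stops <- names(gc_map)[gc_map == "*"]
    codons <- names(gc_map)[gc_map != "*"]
    .codon_env$tab <- list(codons = codons,
                           aa = unname(gc_map[codons]),
                           stops = stops)
  }
  .codon_env$tab
}

# precomputed classification of all single-nucleotide-change codon pairs:
# 61 x 61 integer matrices, 0 = not a single change, 1 = allowed; plus
# logical matrices for transition and nonsynonymous status
.codon_pairs <- function() {
  if (!is.null(.codon_env$pairs)) return(.codon_env$pairs)
  ab <- codon_alphabet()
  n <- length(ab$codons)
  split_mat <- do.call(rbind, strsplit(ab$codons, ""))
  single <- matrix(FALSE, n, n)
  transition <- matrix(FALSE, n, n)
  nonsyn <- matrix(FALSE, n, n)
  is_ts <- function(a, b) {
    (a %in% c("A", "G") && b %in% c("A", "G")) ||
      (a %in% c("C", "T") && b %in% c("C", "T"))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(split_mat[i, ] != split_mat[j, ])
      if (length(diff) != 1) next
      single[i, j] <- TRUE
      transition[i, j] <- is_ts(split_mat[i, diff], split_mat[j, diff])
      nonsyn[i, j] <- ab$aa[i] != ab$aa[j]
    }
  }
  .codon_env$pairs <- list(single = single, transition = transition,
                           nonsyn = nonsyn)
  .codon_env$pairs
}

#' Build the site-class codon substitution model for one gene
#'
#' Constructs the three per-site-class 61-state rate matrices implied by a
#' gene's sampled parameters. Off-diagonal rates exist only between codons
#' that differ at exactly one nucleotide position (stop codons excluded) and
#' equal `pi_j * kappa^[transition] * omega_c^[nonsynonymous]`. The mixture
#' is normalized so that the class-weighted expected number of substitutions
#' per codon site equals 1 per unit branch length, which makes branch
#' lengths interpretable as expected substitutions per codon site.
#'
#' @param profile a [sample_gene_profile()] result (fields `kappa`, `omega`,
#'   `p`).
#' @param frequencies stationary frequencies over the 61 sense codons;
#'   defaults to equal frequencies 1/61.
#' @return an object of class `codon_model`: list with `Q` (list of three
#'   scaled rate matrices), `exit_rates` (61 x 3 matrix of positive
#'   per-state exit rates), `pi`, `nu` (the normalizer), and the alphabet.
#' @export
#' @examples
#' set.seed(1)
#' pr <- sample_gene_profile(sim_config(), "positive")
#' m <- build_codon_model(pr)
#' # class-mixture expected rate is 1 by construction:
#' sum(pr$p * vapply(1:3, function(c) sum(m$pi * m$exit_rates[, c]), 0))
build_codon_model <- function(profile, frequencies = NULL) {
  ab <- codon_alphabet()
  n <- length(ab$codons)
  if (is.null(frequencies)) frequencies <- rep(1 / n, n)
  if (length(frequencies) != n)
    stop("frequencies must have length 61", call. = FALSE)
  if (abs(sum(frequencies) - 1) > 1e-9)
    stop("frequencies must sum to 1", call. = FALSE)
  if (any(frequencies <= 0))
    stop("frequencies must all be positive", call. = FALSE)
  pairs <- .codon_pairs()
  base <- matrix(0, n, n)
  base[pairs$single] <- 1
  base <- base * matrix(frequencies, n, n, byrow = TRUE)
  base[pairs$single & pairs$transition] <-
    base[pairs$single & pairs$transition] * profile$kappa
  Q <- vector("list", 3)
  for (c in 1:3) {
    Qc <- base
    ns <- pairs$single & pairs$nonsyn
    Qc[ns] <- Qc[ns] * profile$omega[c]
    diag(Qc) <- -rowSums(Qc)
    Q[[c]] <- Qc
  }
  nu <- sum(vapply(1:3, function(c) {
    profile$p[c] * sum(frequencies * -diag(Q[[c]]))
  }, numeric(1)))
  Q <- lapply(Q, function(Qc) Qc / nu)
  exit_rates <- vapply(Q, function(Qc) -diag(Qc), numeric(n))
  structure(list(Q = Q, exit_rates = exit_rates, pi = frequencies,
                 nu = nu, codons = ab$codons, aa = ab$aa),
            class = "codon_model")
}

#' @export
print.codon_model <- function(x, ...) {
  cat("Site-class codon substitution model (61 sense codons)\n")
  cat(sprintf("  normalizer nu = %.4f; mixture rate scaled to 1/site/unit length\n",
              x$nu))
  invisible(x)
}
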