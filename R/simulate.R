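#' Simulate one gene along the phylogeny
#'
#' Runs an exact event-level (Gillespie) continuous-time Markov simulation of
#' codon substitution, insertion and deletion along every branch of the
#' tree. The root sequence is drawn site-wise from the stationary codon
#' frequencies with site classes assigned i.i.d. from (p0, p1, p2). Indels
#' act on whole codons (preserving reading frame) with geometric lengths;
#' insertions place new codons drawn from the stationary frequencies with
#' freshly drawn site classes. Homology is tracked through a global column
#' registry so the true alignment is emitted alongside the unaligned leaf
#' sequences.
#'
#' @param profile a [sample_gene_profile()] result.
#' @param tree a [build_symmetric_tree()] phylogeny (any rooted binary
#'   `phylo` with branch lengths works).
#' @param codon_model a [build_codon_model()] result for `profile`.
#' @param config a [sim_config()] object (supplies the indel model).
#' @param gene_id identifier stored in the record.
#' @return an object of class `gene_record`: list with `leaf_seqs` (named
#'   ungapped codon strings in tip order), `alignment` (named gapped rows of
#'   equal length), `annotation` (data frame: 0-based codon `column`, site
#'   `class` S0/S1/S2, `omega`, logical `inserted`), `counts`
#'   (substitutions, insertions, deletions), `events` (per-event indel
#'   lengths), `profile` and `label`.
#' @export
#' @examples
#' set.seed(7)
#' cfg <- sim_config()
#' pr <- sample_gene_profile(cfg, "purifying")
#' rec <- simulate_gene(pr, build_symmetric_tree(8, 0.2),
#'                      build_codon_model(pr), cfg)
#' rec$counts
simulate_gene <- function(profile, tree, codon_model, config,
                          gene_id = "gene") {
  stopifnot(inherits(profile, "gene_profile"),
            inherits(codon_model, "codon_model"),
            inherits(config, "sim_config"))
  if (length(tree$tip.label) < 2)
    stop("tree must have at least 2 leaves", call. = FALSE)
  r <- config$indel_rate
  rho <- config$ins_del_ratio
  ins_rate <- r * rho / (1 + rho)
  del_rate <- r / (1 + rho)
  qg <- config$indel_geom_q
  L0 <- profile$root_length
  pi <- codon_model$pi

  st <- new.env(parent = emptyenv())
  st$registry <- seq_len(L0)
  st$id_class <- sample.int(3, L0, replace = TRUE, prob = profile$p)
  st$next_id <- L0 + 1L
  st$n_sub <- 0L; st$n_ins <- 0L; st$n_del <- 0L
  st$ins_len <- integer(0)
  st$del_requested <- integer(0); st$del_applied <- integer(0)
  st$leaf <- vector("list", length(tree$tip.label))

  root_states <- sample.int(61, L0, replace = TRUE, prob = pi)
  root_classes <- st$id_class
  kids <- .tree_children(tree)
  blen_of <- function(child) {
    tree$edge.length[which(tree$edge[, 2] == child)]
  }

  descend <- function(node, states, classes, ids) {
    if (is.null(kids[[node]])) {
      st$leaf[[node]] <- list(states = states, ids = ids)
      return(invisible(NULL))
    }
    for (child in kids[[node]]) {
      res <- .evolve_branch_cpp(states, classes, ids, blen_of(child),
                                codon_model$Q, codon_model$exit_rates,
                                pi, profile$p, ins_rate, del_rate, qg,
                                st$next_id)
      st$next_id <- res$next_id
      st$n_sub <- st$n_sub + res$n_sub
      st$n_ins <- st$n_ins + res$n_ins
      st$n_del <- st$n_del + res$n_del
      st$ins_len <- c(st$ins_len, res$ins_len)
      st$del_requested <- c(st$del_requested, res$del_requested)
      st$del_applied <- c(st$del_applied, res$del_applied)
      if (length(res$ins_anchor)) {
        for (k in seq_along(res$ins_anchor)) {
          anchor <- res$ins_anchor[k]
          new_ids <- res$ins_ids[[k]]
          pos <- if (anchor == 0L) 0L else match(anchor, st$registry)
          st$registry <- append(st$registry, new_ids, after = pos)
          st$id_class[new_ids] <- res$ins_classes[[k]]
        }
      }
      descend(child, res$states, res$classes, res$ids)
    }
  }
  descend(.tree_root(tree), root_states, root_classes, st$registry)

  codons <- codon_model$codons
  n_tip <- length(tree$tip.label)
  present <- unique(unlist(lapply(st$leaf, `[[`, "ids")))
  keep <- st$registry[st$registry %in% present]
  m <- length(keep)
  aln <- character(n_tip)
  leaf_seqs <- character(n_tip)
  for (t in seq_len(n_tip)) {
    row <- rep("---", m)
    idx <- match(st$leaf[[t]]$ids, keep)
    row[idx] <- codons[st$leaf[[t]]$states]
    aln[t] <- paste(row, collapse = "")
    leaf_seqs[t] <- paste(codons[st$leaf[[t]]$states], collapse = "")
  }
  names(aln) <- names(leaf_seqs) <- tree$tip.label
  cls <- st$id_class[keep]
  annotation <- data.frame(column = seq_len(m) - 1L,
                           class = paste0("S", cls - 1L),
                           omega = profile$omega[cls],
                           inserted = keep > L0)
  structure(list(gene_id = gene_id, profile = profile,
                 leaf_seqs = leaf_seqs, alignment = aln,
                 annotation = annotation,
                 counts = list(substitutions = st$n_sub,
                               insertions = st$n_ins,
                               deletions = st$n_del),
                 events = list(ins_len = st$ins_len,
                               del_requested = st$del_requested,
                               del_applied = st$del_applied),
                 label = profile$label),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("Gene record '%s' (%s, label %d)\n", x$gene_id,
              x$profile$gene_class, x$label))
  cat(sprintf("  %d taxa, true alignment %d codon columns\n",
              length(x$alignment), nrow(x$annotation)))
  cat(sprintf("  events: %d substitutions, %d insertions, %d deletions\n",
              x$counts$substitutions, x$counts$insertions,
              x$counts$deletions))
  invisible(x)
}

# deterministic proportional class allocation with round-robin interleaving;
# remainder codons go to the largest class
.allocate_classes <- function(mix, n) {
  counts <- floor(mix * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[which.max(mix)] <- counts[which.max(mix)] + rem
  counts <- counts[counts > 0]
  pos <- unlist(lapply(names(counts), function(cl) {
    stats::setNames((seq_len(counts[[cl]]) - 0.5) / counts[[cl]],
                    rep(cl, counts[[cl]]))
  }))
  names(pos)[order(pos, names(pos))]
}

# per-gene RNG substream seed derived from the master seed by counter
.gene_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + i * 104729) %% 2147483647
}

#' Simulate a labelled dataset of genes
#'
#' Generates `n_genes` gene records under the configured class mix. Gene
#' classes are allocated deterministically so class counts match the
#' configured proportions exactly (round-robin interleaving, remainder to
#' the largest class); each gene is simulated from an independent RNG
#' substream derived from the master seed by counter, so datasets are
#' reproducible and per-gene results do not depend on simulation order.
#'
#' @param config a [sim_config()] object.
#' @param n_genes number of genes (>= 1).
#' @param seed master seed (integer).
#' @param dir optional directory; when given the dataset is written out via
#'   [write_dataset()].
#' @return an object of class `sim_dataset`: list with `records` (list of
#'   `gene_record`), `manifest` (data frame), `tree`, and `config`.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(), n_genes = 4, seed = 1)
#' ds$manifest[, c("gene_id", "class", "label")]
simulate_dataset <- function(config, n_genes, seed = 1, dir = NULL) {
  validate_sim_config(config)
  if (n_genes < 1) stop("n_genes must be >= 1", call. = FALSE)
  classes <- .allocate_classes(config$class_mix, n_genes)
  tree <- build_symmetric_tree(config$n_taxa, config$divergence)
  records <- vector("list", n_genes)
  rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gseed <- .gene_seed(seed, i)
    set.seed(gseed)
    gene_id <- sprintf("gene%05d", i)
    profile <- sample_gene_profile(config, classes[i])
    model <- build_codon_model(profile, config$codon_freqs)
    records[[i]] <- simulate_gene(profile, tree, model, config, gene_id)
    rows[[i]] <- data.frame(gene_id = gene_id, class = classes[i],
                            label = profile$label, kappa = profile$kappa,
                            omega0 = profile$omega[1],
                            omega1 = profile$omega[2],
                            omega2 = profile$omega[3],
                            p0 = profile$p[1], p1 = profile$p[2],
                            p2 = profile$p[3],
                            root_length = profile$root_length,
                            seed = gseed)
  }
  out <- structure(list(records = records,
                        manifest = do.call(rbind, rows),
                        tree = tree, config = config),
                   class = "sim_dataset")
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d genes (%d labelled positive)\n",
              length(x$records), sum(x$manifest$label)))
  print(x$config)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Lays out the standard dataset directory: `unaligned/<gene>.fasta`,
#' `true_alignment/<gene>.fasta`, `annotations/<gene>.tsv`, `tree.nwk`, and
#' `manifest.tsv`.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  for (sub in c("unaligned", "true_alignment", "annotations"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (rec in dataset$records) {
    write_fasta(rec$leaf_seqs,
                file.path(dir, "unaligned", paste0(rec$gene_id, ".fasta")))
    write_fasta(rec$alignment,
                file.path(dir, "true_alignment",
                          paste0(rec$gene_id, ".fasta")))
    utils::write.table(rec$annotation,
                       file.path(dir, "annotations",
                                 paste0(rec$gene_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  utils::write.table(dataset$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
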