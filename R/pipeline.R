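# Configuration-driven pipeline: simulate -> encode -> train -> predict ->
# evaluate, with a resolved-config snapshot for reproducibility. The
# command-line entry point (inst/cli/selcnn.R) is a thin wrapper over these
# functions.

#' Encode a simulated dataset
#'
#' One-hot encodes the true alignments of a dataset (or any list of gene
#' records) into `encoded_example` objects, carrying labels and gene ids.
#'
#' @param x a `sim_dataset`, a list of `gene_record` objects, or a dataset
#'   directory written by [write_dataset()].
#' @return list of `encoded_example` objects.
#' @export
encode_dataset <- function(x) {
  if (is.character(x)) {
    manifest <- utils::read.table(file.path(x, "manifest.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    return(lapply(seq_len(nrow(manifest)), function(i) {
      msa <- read_fasta(file.path(x, "true_alignment",
                                  paste0(manifest$gene_id[i], ".fasta")),
                        msa = TRUE)
      encode_msa(msa, manifest$label[i], manifest$gene_id[i])
    }))
  }
  records <- if (inherits(x, "sim_dataset")) x$records else x
  lapply(records, function(rec) {
    encode_msa(rec$alignment, rec$label, rec$gene_id)
  })
}

#' Default pipeline configuration
#'
#' Desk-scale defaults: a 200-gene training set, a 50-gene test set, and a
#' short training run with reduced filter counts. The simulation block
#' carries the baseline evolutionary parameters of [sim_config()]. The
#' full-scale regime (1,000,000 genes, 50 epochs, batch 512, full filter
#' counts) is available as the `"paper_scale"` preset of
#' [pipeline_preset()].
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(seed = 1,
       out_dir = NULL,
       simulation = list(n_genes = 200, n_test = 50,
                         n_taxa = 8, divergence = 0.2,
                         indel_rate = 0.1, ins_del_ratio = 1,
                         indel_geom_q = 0.35,
                         class_mix = c(purifying = 0.4, neutral = 0.1,
                                       positive = 0.5),
                         root_length_range = c(100, 600)),
       training = list(filters = c(8, 8, 16, 16, 32, 32, 64),
                       dense_width = 16, dropout = 0.5,
                       learning_rate = 0.001, batch_size = 32,
                       epochs = 2, val_fraction = 0.05,
                       shuffle_rows = FALSE),
       evaluation = list(threshold = 0.5))
}

#' Named pipeline presets
#'
#' @param name `"smoke"` (the desk-scale default) or `"paper_scale"` (the
#'   full training regime: 1,000,000 genes, batch 512, 50 epochs, full
#'   filter counts; documented for completeness, not exercised by the test
#'   suite).
#' @return configuration list for [run_pipeline()].
#' @export
pipeline_preset <- function(name = c("smoke", "paper_scale")) {
  name <- match.arg(name)
  cfg <- default_run_config()
  if (name == "paper_scale") {
    cfg$simulation$n_genes <- 1000000
    cfg$simulation$n_test <- 2000
    cfg$training <- list(filters = c(32, 32, 64, 64, 128, 128, 256),
                         dense_width = 64, dropout = 0.5,
                         learning_rate = 0.001, batch_size = 512,
                         epochs = 50, val_fraction = 0.05,
                         shuffle_rows = FALSE)
  }
  cfg
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!(key %in% names(defaults)))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
        !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a pipeline configuration file
#'
#' Reads a YAML configuration and merges it over [default_run_config()];
#' unknown keys are rejected with the offending key named.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(default_run_config(), user)
  if (!is.null(cfg$simulation$class_mix))
    cfg$simulation$class_mix <- unlist(cfg$simulation$class_mix)
  cfg
}

.sim_config_from <- function(block) {
  args <- block[setdiff(names(block), c("n_genes", "n_test"))]
  do.call(sim_config, args)
}

.cnn_spec_from <- function(block, n_taxa, seed) {
  do.call(cnn_spec, c(block, list(n_taxa = n_taxa, seed = seed)))
}

#' Run the full pipeline
#'
#' Chains simulate -> encode -> train -> predict -> evaluate under one
#' configuration and seed. Training and test sets are simulated from
#' disjoint seed substreams. When `config$out_dir` is set, the resolved
#' configuration snapshot (YAML), the training history, per-gene test
#' scores and the metrics report (JSON-like YAML) are written there.
#'
#' @param config nested list as from [default_run_config()] or
#'   [load_run_config()].
#' @param verbose print stage progress.
#' @return list with `model`, `report`, `scores`, `test_manifest`, and
#'   `config` (resolved).
#' @export
run_pipeline <- function(config = default_run_config(), verbose = FALSE) {
  config <- .merge_config(default_run_config(), config)
  sim_cfg <- .sim_config_from(config$simulation)
  seed <- config$seed
  if (verbose) message("simulating ", config$simulation$n_genes,
                       " training genes")
  train_ds <- simulate_dataset(sim_cfg, config$simulation$n_genes,
                               seed = seed)
  if (verbose) message("simulating ", config$simulation$n_test,
                       " test genes")
  test_ds <- simulate_dataset(sim_cfg, config$simulation$n_test,
                              seed = seed + 500000)
  train_ex <- encode_dataset(train_ds)
  test_ex <- encode_dataset(test_ds)
  spec <- .cnn_spec_from(config$training, sim_cfg$n_taxa, seed)
  if (verbose) message("training for ", spec$epochs, " epochs")
  model <- omega_cnn(train_ex, spec, verbose = verbose)
  scores <- predict(model, test_ex)
  report <- compute_report(scores, test_ds$manifest$label,
                           config$evaluation$threshold)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    snap <- config
    snap$simulation$class_mix <- as.list(snap$simulation$class_mix)
    yaml::write_yaml(snap, file.path(config$out_dir,
                                     "resolved_config.yaml"))
    utils::write.table(model$history,
                       file.path(config$out_dir, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(gene_id = names(scores),
                                  score = as.numeric(scores),
                                  label = test_ds$manifest$label),
                       file.path(config$out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(report[c("threshold", "TP", "TN", "FP", "FN", "n",
                              "accuracy", "tpr", "fpr", "precision",
                              "recall", "roc_auc", "pr_auc")],
                     file.path(config$out_dir, "report.yaml"))
  }
  list(model = model, report = report, scores = scores,
       test_manifest = test_ds$manifest, config = config)
}
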