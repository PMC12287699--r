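# Shared fixtures. Heavy simulations/trainings are memoised so several test
# files can share one computation.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# small genes for fast structural tests: short roots via a small gamma
small_sim_config <- function(...) {
  sim_config(root_length_shape = 4.2, root_length_scale = 12,
             root_length_range = c(30, 80), ...)
}

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_taxa = 8, filters = c(4, 4, 8), dense_width = 8,
                   batch_size = 8, epochs = 1, val_fraction = 0,
                   seed = 7)
  do.call(cnn_spec, utils::modifyList(defaults, args))
}

random_msa <- function(n = 8, L = 30, gaps = TRUE) {
  alphabet <- c("A", "C", "G", "T", if (gaps) "-")
  rows <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), "")
  names(rows) <- paste0("t", seq_len(n))
  rows
}

random_examples <- function(k, n = 8, Ls = c(30, 60, 90)) {
  lapply(seq_len(k), function(i) {
    encode_msa(random_msa(n, sample(Ls, 1)),
               label = i %% 2, gene_id = sprintf("g%03d", i))
  })
}

# a gene_profile with chosen parameters (bypasses sampling)
fixed_profile <- function(kappa = 2, omega = c(0.3, 0.7, 2),
                          p = c(0.6, 0.35, 0.05), root_length = 50L,
                          gene_class = "positive") {
  structure(list(kappa = kappa, omega = omega, p = p,
                 root_length = as.integer(root_length),
                 gene_class = gene_class,
                 label = as.integer(gene_class == "positive")),
            class = "gene_profile")
}

# 300 genes under baseline conditions; shared by the indel-calibration and
# geometric-length checks
baseline_300 <- function() {
  cached("baseline_300", simulate_dataset(sim_config(), 300, seed = 20260926))
}

# small dataset for round-trip / invariance checks
small_dataset_20 <- function() {
  cached("small_dataset_20",
         simulate_dataset(small_sim_config(), 20, seed = 77))
}

# The scaled-down learning run: 1,000 training genes and 1,000 held-out
# genes with root lengths 100-150 codons under otherwise-baseline
# conditions, a reduced-filter model trained for 15 epochs, and a control
# model trained on permuted labels.
scaled_run <- function() {
  cached("scaled_run", {
    cfg <- sim_config(root_length_range = c(100, 150))
    train_ds <- simulate_dataset(cfg, 1000, seed = 101)
    test_ds <- simulate_dataset(cfg, 1000, seed = 900101)
    train_ex <- encode_dataset(train_ds)
    test_ex <- encode_dataset(test_ds)
    spec <- cnn_spec(filters = c(8, 8, 16, 16, 32, 32, 64),
                     dense_width = 16, dropout = 0, learning_rate = 0.003,
                     batch_size = 32, epochs = 15, val_fraction = 0.05,
                     shuffle_rows = TRUE, seed = 1)
    model <- omega_cnn(train_ex, spec)
    scores <- predict(model, test_ex)
    # permuted-label control: same data, labels shuffled once
    set.seed(555)
    perm <- sample.int(length(train_ex))
    control_ex <- lapply(seq_along(train_ex), function(i) {
      ex <- train_ex[[i]]
      ex$label <- train_ex[[perm[i]]]$label
      ex
    })
    control <- omega_cnn(control_ex, spec)
    control_scores <- predict(control, test_ex)
    list(model = model, scores = scores,
         labels = test_ds$manifest$label,
         control_scores = control_scores,
         test_ds = test_ds, test_ex = test_ex)
  })
}
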