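#' Architecture and training specification for the codon-aware CNN
#'
#' Defines the classifier: a first convolution with an `n_taxa x 3` filter
#' applied with stride 3 along nucleotide columns (one codon column per
#' step), followed by further width-`kernel_width` convolutions over codon
#' columns, each block being conv -> ReLU -> batch normalization -> dropout
#' -> average pooling; then global average pooling over columns, a dense
#' ReLU layer, and a single sigmoid output unit. Defaults follow the
#' reference training regime: seven convolutional layers, dropout 0.5, Adam
#' with learning rate 0.001, batch size 512, 50 epochs, 5% validation
#' split. Per-layer filter counts and the dense width are tunable defaults
#' of this package, not fixed constants of the approach.
#'
#' @param n_taxa alignment rows the model accepts.
#' @param filters convolutional filter counts, one per layer (length =
#'   number of conv layers, default 7).
#' @param dense_width hidden units of the fully connected layer.
#' @param kernel_width odd column width of conv layers after the first.
#' @param pool_width average-pooling width (= stride, floor semantics;
#'   pooling is skipped once fewer positions remain).
#' @param dropout dropout probability in [0, 1).
#' @param learning_rate Adam step size.
#' @param batch_size alignments per training batch.
#' @param epochs full passes over the training split.
#' @param val_fraction fraction of examples held out for validation.
#' @param shuffle_rows independently permute each example's rows per epoch
#'   (withholds tree information).
#' @param seed seed for Glorot-uniform initialization and training
#'   stochasticity.
#' @return an object of class `cnn_spec`.
#' @export
#' @examples
#' spec <- cnn_spec()
#' length(spec$filters)  # 7 convolutional layers
cnn_spec <- function(n_taxa = 8,
                     filters = c(32, 32, 64, 64, 128, 128, 256),
                     dense_width = 64,
                     kernel_width = 3,
                     pool_width = 2,
                     dropout = 0.5,
                     learning_rate = 0.001,
                     batch_size = 512,
                     epochs = 50,
                     val_fraction = 0.05,
                     shuffle_rows = FALSE,
                     seed = 1) {
  if (length(filters) < 1 || any(filters < 1))
    stop("filters must contain at least one positive count", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  if (kernel_width < 1 || kernel_width %% 2 != 1)
    stop("kernel_width must be a positive odd number", call. = FALSE)
  if (pool_width < 1) stop("pool_width must be >= 1", call. = FALSE)
  if (dense_width < 1) stop("dense_width must be >= 1", call. = FALSE)
  structure(list(n_taxa = n_taxa, filters = as.integer(filters),
                 dense_width = as.integer(dense_width),
                 kernel_width = as.integer(kernel_width),
                 pool_width = as.integer(pool_width), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 val_fraction = val_fraction,
                 shuffle_rows = shuffle_rows, seed = seed),
            class = "cnn_spec")
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat("CNN specification\n")
  cat(sprintf("  input: %d taxa x L x 5 channels\n", x$n_taxa))
  cat(sprintf("  conv layers: %d (filters %s); first filter %d x 3, stride 3\n",
              length(x$filters), paste(x$filters, collapse = "/"),
              x$n_taxa))
  cat(sprintf("  dense %d -> sigmoid; dropout %.2f\n", x$dense_width,
              x$dropout))
  cat(sprintf("  Adam lr %g, batch %d, %d epochs, val fraction %g\n",
              x$learning_rate, x$batch_size, x$epochs, x$val_fraction))
  invisible(x)
}

# Glorot-uniform initialized parameter set for a spec
.init_params <- function(spec) {
  nl <- length(spec$filters)
  conv <- vector("list", nl)
  bn <- vector("list", nl)
  in_dim <- spec$n_taxa * 3 * 5
  for (l in seq_len(nl)) {
    f <- spec$filters[l]
    conv[[l]] <- list(W = .glorot(in_dim, f), b = numeric(f))
    bn[[l]] <- list(gamma = rep(1, f), beta = numeric(f))
    in_dim <- spec$kernel_width * f
  }
  dense <- list(W = .glorot(spec$filters[nl], spec$dense_width),
                b = numeric(spec$dense_width))
  out <- list(W = .glorot(spec$dense_width, 1), b = numeric(1))
  list(conv = conv, bn = bn, dense = dense, out = out)
}

.init_bn_state <- function(spec) {
  lapply(spec$filters, function(f) list(rmean = numeric(f), rvar = rep(1, f)))
}

#' Build an untrained CNN
#'
#' Instantiates the model described by a [cnn_spec()], with parameters drawn
#' from the Glorot-uniform scheme using the spec's seed. The returned object
#' supports [predict()] (scores from random weights) and is the starting
#' point of [omega_cnn()] training.
#'
#' @param spec a [cnn_spec()].
#' @param seed overrides `spec$seed` for initialization when given.
#' @return an object of class `omega_cnn` with `trained = FALSE`.
#' @export
build_cnn <- function(spec = cnn_spec(), seed = NULL) {
  stopifnot(inherits(spec, "cnn_spec"))
  if (!is.null(seed)) spec$seed <- seed
  set.seed(spec$seed)
  structure(list(spec = spec, params = .init_params(spec),
                 bn_state = .init_bn_state(spec),
                 history = NULL, trained = FALSE),
            class = "omega_cnn")
}

# full forward pass over a batch tensor (B, n, L, 5); `lengths` gives each
# example's true (unpadded) nucleotide column count, defaulting to full
.net_forward <- function(params, bn_state, spec, x, training = FALSE,
                         lengths = NULL) {
  d <- dim(x)
  if (length(d) != 4 || d[2] != spec$n_taxa || d[4] != 5)
    stop("shape error: input must be B x ", spec$n_taxa, " x L x 5",
         call. = FALSE)
  if (d[3] %% 3 != 0)
    stop("shape error: column count not divisible by 3", call. = FALSE)
  B <- d[1]
  nl <- length(spec$filters)
  caches <- vector("list", nl)
  new_bn <- bn_state
  m <- d[3] %/% 3
  valid <- if (is.null(lengths)) rep(m, B) else pmin(lengths %/% 3, m)
  for (l in seq_len(nl)) {
    if (l == 1) {
      cv <- .conv1_forward(x, params$conv[[1]]$W, params$conv[[1]]$b)
    } else {
      cv <- .convk_forward(X, params$conv[[l]]$W, params$conv[[l]]$b,
                           B, m, spec$kernel_width)
    }
    rl <- .relu_forward(cv$out)
    bnr <- .bn_forward(rl$out, params$bn[[l]]$gamma, params$bn[[l]]$beta,
                       bn_state[[l]]$rmean, bn_state[[l]]$rvar, training)
    new_bn[[l]] <- list(rmean = bnr$rmean, rvar = bnr$rvar)
    dr <- .dropout_forward(bnr$out, spec$dropout, training)
    pl <- .pool_forward(dr$out, B, m, spec$pool_width)
    caches[[l]] <- list(conv = cv$cache, relu = rl$cache, bn = bnr$cache,
                        drop = dr$cache, pool = pl$cache, m_in = m)
    X <- pl$out
    if (!pl$cache$identity)
      valid <- pmin(pl$cache$m_out, ceiling(valid / spec$pool_width))
    m <- pl$cache$m_out
  }
  gp <- .global_pool_forward(X, B, m, valid)
  de <- .dense_forward(gp$out, params$dense$W, params$dense$b)
  dr <- .relu_forward(de$out)
  fo <- .dense_forward(dr$out, params$out$W, params$out$b)
  Z <- .sigmoid(fo$out)
  list(Z = as.numeric(Z), z_pre = as.numeric(fo$out),
       caches = list(blocks = caches, gp = gp$cache, dense = de$cache,
                     drelu = dr$cache, out = fo$cache, B = B),
       bn_state = new_bn)
}

# backward pass; d_zpre is dLoss/d(pre-sigmoid output), length B
.net_backward <- function(params, spec, fw, d_zpre,
                          want_input_grad = FALSE) {
  cc <- fw$caches
  nl <- length(spec$filters)
  grads <- list(conv = vector("list", nl), bn = vector("list", nl))
  dfo <- matrix(d_zpre, ncol = 1)
  bo <- .dense_backward(dfo, cc$out)
  dDr <- .relu_backward(bo$dX, cc$drelu)
  bd <- .dense_backward(dDr, cc$dense)
  # assembled in the same order as the parameter list (conv, bn, dense, out)
  grads$dense <- list(W = bd$dW, b = bd$db)
  grads$out <- list(W = bo$dW, b = bo$db)
  dX <- .global_pool_backward(bd$dX, cc$gp)
  dxin <- NULL
  for (l in rev(seq_len(nl))) {
    blk <- cc$blocks[[l]]
    dX <- .pool_backward(dX, blk$pool)
    dX <- .dropout_backward(dX, blk$drop)
    bnb <- .bn_backward(dX, blk$bn)
    grads$bn[[l]] <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
    dH <- .relu_backward(bnb$dX, blk$relu)
    if (l == 1) {
      cb <- .conv1_backward(dH, blk$conv, want_input_grad)
      grads$conv[[1]] <- list(W = cb$dW, b = cb$db)
      if (want_input_grad) dxin <- cb$dx
    } else {
      cb <- .convk_backward(dH, blk$conv)
      grads$conv[[l]] <- list(W = cb$dW, b = cb$db)
      dX <- cb$dx
    }
  }
  list(grads = grads, dx = dxin)
}

# ---- Adam ---------------------------------------------------------------

.adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk)
    else list(m = p * 0, v = p * 0)
  }
  walk(params)
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (k in keys) {
        r <- walk(p[[k]], g[[k]], s[[k]])
        p[[k]] <- r$p
        s[[k]] <- r$s
      }
      return(list(p = p, s = s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mh <- s$m / (1 - beta1^t)
    vh <- s$v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
  walk(params, grads, state)
}

.bce_loss <- function(Z, y) {
  Zc <- pmin(pmax(Z, 1e-12), 1 - 1e-12)
  -mean(y * log(Zc) + (1 - y) * log(1 - Zc))
}

#' Fit the positive-selection CNN
#'
#' Trains the convolutional classifier on encoded alignments with Adam and
#' a binary cross-entropy loss. Examples are split into training and
#' validation sets by `spec$val_fraction`; each epoch reshuffles the
#' training split into zero-padded batches and performs one full pass; the
#' returned model is the final-epoch model (no early stopping). All
#' stochasticity (initialization, shuffling, dropout) derives from
#' `spec$seed`, so identical calls reproduce identical histories.
#'
#' @param x list of `encoded_example` objects (see [encode_msa()]), or the
#'   path of a [write_records()] file.
#' @param spec a [cnn_spec()].
#' @param verbose print per-epoch progress.
#' @return an object of class `omega_cnn`: list with `spec`, `params`,
#'   `bn_state`, `history` (per-epoch data frame with train/validation loss
#'   and accuracy), `trained = TRUE`.
#' @seealso [predict.omega_cnn()], [saliency_map()], [compute_report()]
#' @export
omega_cnn <- function(x, spec = cnn_spec(), verbose = FALSE) {
  examples <- if (is.character(x)) read_records(x) else x
  if (!length(examples) || !inherits(examples[[1]], "encoded_example"))
    stop("x must be a list of encoded examples or a records file path",
         call. = FALSE)
  labels <- vapply(examples, `[[`, 0L, "label")
  model <- build_cnn(spec)  # seeds the RNG stream
  n_val <- floor(spec$val_fraction * length(examples))
  perm <- sample.int(length(examples))
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(perm, val_idx)
  if (length(unique(labels[train_idx])) < 2)
    stop("degenerate training data: a single class in the training split",
         call. = FALSE)
  train <- examples[train_idx]
  val <- examples[val_idx]
  params <- model$params
  bn_state <- model$bn_state
  adam <- .adam_init(params)
  t_step <- 0L
  hist <- vector("list", spec$epochs)
  for (epoch in seq_len(spec$epochs)) {
    batches <- make_batches(train, spec$batch_size,
                            shuffle_rows = spec$shuffle_rows,
                            shuffle = TRUE)
    ep_loss <- 0; ep_correct <- 0
    for (bt in batches) {
      fw <- .net_forward(params, bn_state, spec, bt$tensor,
                         training = TRUE, lengths = bt$lengths)
      bn_state <- fw$bn_state
      B <- length(bt$labels)
      ep_loss <- ep_loss + .bce_loss(fw$Z, bt$labels) * B
      ep_correct <- ep_correct + sum((fw$Z >= 0.5) == (bt$labels == 1))
      d_zpre <- (fw$Z - bt$labels) / B
      bw <- .net_backward(params, spec, fw, d_zpre)
      t_step <- t_step + 1L
      st <- .adam_step(params, bw$grads, adam, spec$learning_rate, t_step)
      params <- st$p
      adam <- st$s
    }
    model$params <- params
    model$bn_state <- bn_state
    val_loss <- NA_real_; val_acc <- NA_real_
    if (length(val)) {
      vz <- .predict_examples(model, val)
      vy <- vapply(val, `[[`, 0L, "label")
      val_loss <- .bce_loss(vz, vy)
      val_acc <- mean((vz >= 0.5) == (vy == 1))
    }
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = ep_loss / length(train),
                                train_acc = ep_correct / length(train),
                                val_loss = val_loss, val_acc = val_acc)
    if (verbose)
      message(sprintf("epoch %d/%d: train loss %.4f acc %.3f%s",
                      epoch, spec$epochs, ep_loss / length(train),
                      ep_correct / length(train),
                      if (length(val))
                        sprintf(" | val loss %.4f acc %.3f",
                                val_loss, val_acc) else ""))
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

# inference: batch-norm in running-stats mode, dropout off. Examples are
# grouped by alignment length so no cross-example padding is introduced and
# scores are invariant to how the input is partitioned into batches.
.predict_examples <- function(model, examples, max_batch = 256L) {
  n_taxa <- model$spec$n_taxa
  bad <- vapply(examples, `[[`, 0L, "n") != n_taxa
  if (any(bad))
    stop("shape error: examples have ", examples[[which(bad)[1]]]$n,
         " rows but the model expects ", n_taxa, call. = FALSE)
  Ls <- vapply(examples, `[[`, 0L, "L")
  scores <- numeric(length(examples))
  for (L in unique(Ls)) {
    idx <- which(Ls == L)
    for (s in seq(1, length(idx), by = max_batch)) {
      sub <- idx[s:min(s + max_batch - 1, length(idx))]
      tensor <- array(0, dim = c(length(sub), n_taxa, L, 5))
      for (b in seq_along(sub)) tensor[b, , , ] <- examples[[sub[b]]]$tensor
      fw <- .net_forward(model$params, model$bn_state, model$spec, tensor,
                         training = FALSE)
      scores[sub] <- fw$Z
    }
  }
  scores
}

#' Predict selection scores for encoded alignments
#'
#' Applies the trained (or freshly initialized) classifier in inference
#' mode: dropout inactive, batch normalization using running statistics.
#' Scores are order-preserving and invariant to batch partitioning.
#'
#' @param object an `omega_cnn` model.
#' @param newdata list of `encoded_example` objects, a single
#'   `encoded_example`, or a records file path.
#' @param type `"score"` for sigmoid outputs in [0, 1], `"class"` for
#'   thresholded 0/1 labels.
#' @param threshold decision threshold used when `type = "class"`; a score
#'   `>= threshold` is called positive selection.
#' @param ... unused.
#' @return named numeric (scores) or integer (classes) vector.
#' @export
predict.omega_cnn <- function(object, newdata, type = c("score", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.character(newdata)) newdata <- read_records(newdata)
  if (inherits(newdata, "encoded_example")) newdata <- list(newdata)
  scores <- .predict_examples(object, newdata)
  names(scores) <- vapply(newdata, `[[`, "", "gene_id")
  if (type == "score") scores else classify(scores, threshold)
}

#' @export
print.omega_cnn <- function(x, ...) {
  cat(sprintf("Codon-aware CNN selection classifier (%s)\n",
              if (x$trained) "trained" else "untrained"))
  print(x$spec)
  if (x$trained) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  after %d epochs: train loss %.4f, train acc %.3f",
                last$epoch, last$train_loss, last$train_acc))
    if (!is.na(last$val_acc))
      cat(sprintf(", val acc %.3f", last$val_acc))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.omega_cnn <- function(object, ...) {
  n_par <- 0
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else n_par <<- n_par + length(p)
  }
  walk(object$params)
  cat("Layer stack:\n")
  nl <- length(object$spec$filters)
  cat(sprintf("  1. conv %dx3 stride 3 -> %d filters [ReLU, BN, dropout, pool]\n",
              object$spec$n_taxa, object$spec$filters[1]))
  for (l in seq_len(nl)[-1])
    cat(sprintf("  %d. conv 1x%d -> %d filters [ReLU, BN, dropout, pool]\n",
                l, object$spec$kernel_width, object$spec$filters[l]))
  cat(sprintf("  global average pool -> dense %d (ReLU) -> sigmoid\n",
              object$spec$dense_width))
  cat(sprintf("  %d trainable parameters\n", n_par))
  if (object$trained) {
    cat("Training history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Plot training history
#'
#' @param x a trained `omega_cnn`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.omega_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Training history", ...)
  if (!all(is.na(h$val_loss))) {
    lines(h$epoch, h$val_loss, lty = 2)
    legend("topright", legend = c("train", "validation"), lty = 1:2,
           bty = "n")
  }
  invisible(x)
}
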