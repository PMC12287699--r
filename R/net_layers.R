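# Layer primitives for the codon-aware CNN: forward passes with caches and
# exact backward passes, written over base-R matrix products (BLAS).
#
# Column-position activations are carried as a matrix of shape (B*m, C)
# where B is the batch size, m the number of codon-column positions and C
# the channel count. Rows are ordered batch-fastest: row index = b + B*(j-1)
# for batch element b at position j, so shifting the whole matrix by B rows
# shifts every example by one column position.

.glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

# ---- first layer: n x 3 filter, stride 3 over nucleotide columns ---------

# (B, n, L, 5) -> patch matrix (B*m, n*3*5), m = L/3
.codon_patches <- function(x) {
  d <- dim(x)
  B <- d[1]; n <- d[2]; L <- d[3]
  m <- L %/% 3
  dim(x) <- c(B, n, 3, m, 5)
  x <- aperm(x, c(1, 4, 2, 3, 5))
  dim(x) <- c(B * m, n * 3 * 5)
  x
}

.codon_patches_rev <- function(dP, B, n, m) {
  dim(dP) <- c(B, m, n, 3, 5)
  dP <- aperm(dP, c(1, 3, 4, 2, 5))
  dim(dP) <- c(B, n, 3 * m, 5)
  dP
}

.conv1_forward <- function(x, W, b) {
  d <- dim(x)
  P <- .codon_patches(x)
  H <- P %*% W
  H <- H + rep(b, each = nrow(H))
  list(out = H, cache = list(P = P, W = W, B = d[1], n = d[2],
                             m = d[3] %/% 3))
}

.conv1_backward <- function(dH, cache, want_input_grad = FALSE) {
  dW <- crossprod(cache$P, dH)
  db <- colSums(dH)
  dx <- NULL
  if (want_input_grad) {
    dP <- tcrossprod(dH, cache$W)
    dx <- .codon_patches_rev(dP, cache$B, cache$n, cache$m)
  }
  list(dW = dW, db = db, dx = dx)
}

# ---- 1D convolution over codon columns, odd width, same padding ----------

.shift_rows <- function(X, B, m, by) {
  # shift every example's positions by `by` columns (zero fill)
  if (by == 0) return(X)
  C <- ncol(X)
  out <- matrix(0, B * m, C)
  if (abs(by) >= m) return(out)
  nkeep <- B * (m - abs(by))
  if (by > 0) {
    out[(B * by + 1):(B * m), ] <- X[1:nkeep, , drop = FALSE]
  } else {
    out[1:nkeep, ] <- X[(B * -by + 1):(B * m), , drop = FALSE]
  }
  out
}

.convk_forward <- function(X, W, b, B, m, k) {
  h <- (k - 1) %/% 2
  C <- ncol(X)
  P <- matrix(0, B * m, k * C)
  for (t in seq_len(k)) {
    P[, ((t - 1) * C + 1):(t * C)] <- .shift_rows(X, B, m, h - (t - 1))
  }
  H <- P %*% W
  H <- H + rep(b, each = nrow(H))
  list(out = H, cache = list(P = P, W = W, B = B, m = m, k = k, C = C))
}

.convk_backward <- function(dH, cache) {
  dW <- crossprod(cache$P, dH)
  db <- colSums(dH)
  dP <- tcrossprod(dH, cache$W)
  h <- (cache$k - 1) %/% 2
  C <- cache$C
  dX <- matrix(0, nrow(dP), C)
  for (t in seq_len(cache$k)) {
    blk <- dP[, ((t - 1) * C + 1):(t * C), drop = FALSE]
    dX <- dX + .shift_rows(blk, cache$B, cache$m, (t - 1) - h)
  }
  list(dW = dW, db = db, dx = dX)
}

# ---- ReLU, batch normalization, dropout, pooling -------------------------

.relu_forward <- function(X) list(out = pmax(X, 0), cache = X > 0)
.relu_backward <- function(dY, cache) dY * cache

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.9

.bn_forward <- function(X, gamma, beta, rmean, rvar, training) {
  if (training) {
    mu <- colMeans(X)
    Xc <- X - rep(mu, each = nrow(X))
    v <- colMeans(Xc * Xc)
    invstd <- 1 / sqrt(v + .BN_EPS)
    xhat <- Xc * rep(invstd, each = nrow(X))
    new_rmean <- .BN_MOMENTUM * rmean + (1 - .BN_MOMENTUM) * mu
    new_rvar <- .BN_MOMENTUM * rvar + (1 - .BN_MOMENTUM) * v
  } else {
    invstd <- 1 / sqrt(rvar + .BN_EPS)
    xhat <- (X - rep(rmean, each = nrow(X))) * rep(invstd, each = nrow(X))
    new_rmean <- rmean
    new_rvar <- rvar
  }
  out <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                    training = training),
       rmean = new_rmean, rvar = new_rvar)
}

.bn_backward <- function(dY, cache) {
  N <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  scale <- cache$gamma * cache$invstd
  if (cache$training) {
    dxhat <- dY * rep(cache$gamma, each = N)
    dX <- (dxhat -
             rep(colMeans(dxhat), each = N) -
             cache$xhat * rep(colMeans(dxhat * cache$xhat), each = N)) *
      rep(cache$invstd, each = N)
  } else {
    dX <- dY * rep(scale, each = N)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

.dropout_forward <- function(X, p, training) {
  if (!training || p <= 0) return(list(out = X, cache = NULL))
  mask <- matrix(runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(out = X * mask, cache = mask)
}

.dropout_backward <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# average pooling over positions, width = stride = w, floor semantics;
# identity when fewer than w positions remain
.pool_forward <- function(X, B, m, w) {
  if (m < w || w <= 1) {
    return(list(out = X, cache = list(identity = TRUE, m_out = m)))
  }
  m2 <- m %/% w
  base <- as.vector(outer(seq_len(B), (w * (seq_len(m2) - 1)) * B, `+`))
  Y <- X[base, , drop = FALSE]
  for (t in seq_len(w - 1)) Y <- Y + X[base + t * B, , drop = FALSE]
  Y <- Y / w
  list(out = Y, cache = list(identity = FALSE, base = base, w = w, B = B,
                             nrow_in = B * m, m_out = m2))
}

.pool_backward <- function(dY, cache) {
  if (cache$identity) return(dY)
  dX <- matrix(0, cache$nrow_in, ncol(dY))
  for (t in seq_len(cache$w) - 1L) {
    dX[cache$base + t * cache$B, ] <- dY / cache$w
  }
  dX
}

# Global average pooling over each example's valid (unpadded) extent:
# positions an example gained only through batch zero-padding are excluded
# from its average, so scores do not depend on batch composition.
.global_pool_forward <- function(X, B, m, valid = NULL) {
  if (is.null(valid)) valid <- rep(m, B)
  grp <- rep_len(seq_len(B), B * m)
  pos <- rep(seq_len(m), each = B)
  mask <- pos <= valid[grp]
  Xm <- X
  Xm[!mask, ] <- 0
  G <- rowsum(Xm, grp) / valid
  list(out = G, cache = list(B = B, m = m, valid = valid, mask = mask,
                             grp = grp))
}

.global_pool_backward <- function(dG, cache) {
  dX <- dG[cache$grp, , drop = FALSE] / cache$valid[cache$grp]
  dX[!cache$mask, ] <- 0
  dX
}

.dense_forward <- function(X, W, b) {
  H <- X %*% W
  H <- H + rep(b, each = nrow(H))
  list(out = H, cache = list(X = X, W = W))
}

.dense_backward <- function(dH, cache) {
  list(dW = crossprod(cache$X, dH), db = colSums(dH),
       dX = tcrossprod(dH, cache$W))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))
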