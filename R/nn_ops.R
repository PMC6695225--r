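# Neural-network primitives with explicit forward/backward passes.
# Everything is vectorised over positions/batches so the heavy lifting is
# matrix multiplication; no external deep-learning framework is used.
#
# Array index conventions (R column-major, first index fastest):
#   embedding input  : integer array, any shape, entries in 0..25
#   column stages    : (ncols, depth, channels) with batch folded into ncols
#   recurrent input  : (batch, time, features)
#   pair trunk input : (L, L, channels), one protein at a time

# ---- initialisation ---------------------------------------------------------

# uniform fan-in scaled init (Glorot-style); draws from the global RNG
.init_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- embedding --------------------------------------------------------------

.emb_forward <- function(idx, W) {
  if (any(idx < 0L) || any(idx >= nrow(W))) {
    stop("residue index outside vocabulary range 0..", nrow(W) - 1L)
  }
  out <- W[as.vector(idx) + 1L, , drop = FALSE]
  array(out, dim = c(dim(idx), ncol(W)))
}

.emb_backward <- function(idx, grad, n_symbols, E) {
  n <- length(idx)
  gmat <- matrix(grad, n, E)
  agg <- rowsum(gmat, group = as.vector(idx))
  dW <- matrix(0, n_symbols, E)
  dW[as.integer(rownames(agg)) + 1L, ] <- agg
  dW
}

#' Embed an integer-coded MSA tensor
#'
#' Looks each integer symbol up in a (continuous, learned) embedding table:
#' every cell with the same index maps to the same E-vector, and the output
#' shape is the input shape with E appended.  Index 0 (padding) has its own
#' embedding row.
#'
#' @param msa_tensor integer array with entries in 0..25 (e.g. a window
#'   width x depth matrix).
#' @param E embedding dimension, used when \code{weights} is NULL.
#' @param weights optional 26 x E embedding matrix (row r = index r-1).
#' @param seed seed for random initialisation when \code{weights} is NULL.
#' @return numeric array of dim \code{c(dim(msa_tensor), E)}.
#' @export
apply_embedding <- function(msa_tensor, E = 10L, weights = NULL, seed = 1L) {
  msa_tensor <- as.array(msa_tensor)
  if (is.null(weights)) {
    old <- .Random.seed_save()
    set.seed(seed)
    weights <- .init_mat(26L, E)
    .Random.seed_restore(old)
  }
  if (nrow(weights) != 26L) stop("embedding weights must have 26 rows")
  .emb_forward(msa_tensor, weights)
}

# ---- column-wise convolution + max pooling ----------------------------------

# forward: x (ncols, D, C), W (k*C, K), b (K); conv along depth only
# ('same' zero padding), ReLU, then max-pool window `pool` stride `pool`.
.colconv_forward <- function(x, W, b, k, pool) {
  dm <- dim(x); ncols <- dm[1L]; D <- dm[2L]; C <- dm[3L]
  K <- length(b)
  left <- (k - 1L) %/% 2L
  xp <- array(0, c(ncols, D + k - 1L, C))
  xp[, left + seq_len(D), ] <- x
  M <- matrix(0, ncols * D, k * C)
  for (t in seq_len(k)) {
    M[, (t - 1L) * C + seq_len(C)] <-
      matrix(xp[, t:(t + D - 1L), ], ncols * D, C)
  }
  Z <- M %*% W + rep(b, each = ncols * D)
  A <- array(pmax(Z, 0), c(ncols, D, K))
  D2 <- D %/% pool
  if (D2 < 1L) stop("alignment depth ", D, " smaller than pool window ", pool)
  A4 <- array(A[, seq_len(D2 * pool), , drop = FALSE], c(ncols, pool, D2, K))
  P <- array(A4[, 1L, , ], c(ncols, D2, K))
  AM <- array(1L, c(ncols, D2, K))
  if (pool > 1L) {
    for (w in 2L:pool) {
      slice <- array(A4[, w, , ], c(ncols, D2, K))
      upd <- slice > P
      P[upd] <- slice[upd]
      AM[upd] <- w
    }
  }
  list(out = P,
       cache = list(M = M, Z = Z, AM = AM, dims = dm, k = k, pool = pool,
                    K = K, left = left, D2 = D2))
}

.colconv_backward <- function(dP, W, cache) {
  dm <- cache$dims; ncols <- dm[1L]; D <- dm[2L]; C <- dm[3L]
  k <- cache$k; pool <- cache$pool; K <- cache$K; D2 <- cache$D2
  dA <- array(0, c(ncols, D, K))
  # un-pool: route gradient to the argmax element of each window
  for (w in seq_len(pool)) {
    sel <- cache$AM == w
    tmp <- array(0, c(ncols, D2, K))
    tmp[sel] <- dP[sel]
    # window w of pooled block d corresponds to depth (d-1)*pool + w
    dA[, (seq_len(D2) - 1L) * pool + w, ] <- tmp
  }
  dZ <- matrix(dA, ncols * D, K) * (cache$Z > 0)
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, W)
  dxp <- array(0, c(ncols, D + k - 1L, C))
  for (t in seq_len(k)) {
    dxp[, t:(t + D - 1L), ] <- dxp[, t:(t + D - 1L), ] +
      array(dM[, (t - 1L) * C + seq_len(C)], c(ncols, D, C))
  }
  dx <- dxp[, cache$left + seq_len(D), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

#' One column-wise convolution + max-pooling stage
#'
#' The convolution filters are column vectors spanning only the alignment
#' (depth) axis, so information never spreads across sequence positions;
#' ReLU activation, then max pooling with the same window and stride reduces
#' the depth from D to floor(D / W).
#'
#' @param x numeric array (width, depth, channels): an embedded window or
#'   full-length MSA.
#' @param window pool/kernel size W along the depth axis (1 x W filters).
#' @param filters number of output filters.
#' @param weights optional list(W, b) with W of dim (window*channels,
#'   filters); random fan-in init when NULL.
#' @param seed RNG seed for the random initialisation.
#' @return numeric array (width, floor(depth/window), filters).
#' @export
column_conv_pool_stage <- function(x, window, filters, weights = NULL,
                                   seed = 1L) {
  x <- as.array(x)
  if (length(dim(x)) != 3L) stop("x must be a (width, depth, channels) array")
  if (dim(x)[2L] < window) {
    stop("alignment depth ", dim(x)[2L], " smaller than window ", window)
  }
  C <- dim(x)[3L]
  if (is.null(weights)) {
    old <- .Random.seed_save()
    set.seed(seed)
    weights <- list(W = .init_mat(window * C, filters),
                    b = rep(0, filters))
    .Random.seed_restore(old)
  }
  .colconv_forward(x, weights$W, weights$b, k = window, pool = window)$out
}

# ---- dense ------------------------------------------------------------------

.dense_forward <- function(x, W, b, relu = TRUE) {
  Z <- x %*% W + rep(b, each = nrow(x))
  out <- if (relu) pmax(Z, 0) else Z
  list(out = out, cache = list(x = x, Z = Z, relu = relu))
}

.dense_backward <- function(dout, W, cache) {
  dZ <- if (cache$relu) dout * (cache$Z > 0) else dout
  list(dx = tcrossprod(dZ, W), dW = crossprod(cache$x, dZ), db = colSums(dZ))
}

# ---- dropout ----------------------------------------------------------------

.dropout_forward <- function(x, p, train) {
  if (!train || p <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= p, dim = dim(x) %||% length(x))
  list(out = x * mask / (1 - p), cache = list(mask = mask, p = p))
}

.dropout_backward <- function(dout, cache) {
  if (is.null(cache)) return(dout)
  dout * cache$mask / (1 - cache$p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- LSTM -------------------------------------------------------------------

.lstm_init <- function(D, U) {
  list(Wx = .init_mat(D, 4L * U), Wh = .init_mat(U, 4L * U),
       b = rep(0, 4L * U))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# x: (B, T, D); returns H: (B, T, U)
.lstm_forward <- function(x, p) {
  dm <- dim(x); B <- dm[1L]; Tn <- dm[2L]; D <- dm[3L]
  U <- nrow(p$Wh)
  H <- array(0, c(B, Tn, U))
  h <- matrix(0, B, U); cc <- matrix(0, B, U)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- matrix(x[, t, ], B, D)
    z <- xt %*% p$Wx + h %*% p$Wh + rep(p$b, each = B)
    i <- .sigmoid(z[, seq_len(U), drop = FALSE])
    f <- .sigmoid(z[, U + seq_len(U), drop = FALSE])
    g <- tanh(z[, 2L * U + seq_len(U), drop = FALSE])
    o <- .sigmoid(z[, 3L * U + seq_len(U), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    H[, t, ] <- h
    steps[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                       c_prev = c_prev, cc = cc, tc = tc, h_prev = h_prev)
  }
  list(out = H, cache = list(steps = steps, B = B, Tn = Tn, D = D, U = U))
}

.lstm_backward <- function(dH, p, cache) {
  B <- cache$B; Tn <- cache$Tn; D <- cache$D; U <- cache$U
  dWx <- matrix(0, D, 4L * U); dWh <- matrix(0, U, 4L * U); db <- rep(0, 4L * U)
  dx <- array(0, c(B, Tn, D))
  dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dh <- matrix(dH[, t, ], B, U) + dh_next
    dc <- dc_next + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g * s$i * (1 - s$i)
    df <- dc * s$c_prev * s$f * (1 - s$f)
    dg <- dc * s$i * (1 - s$g^2)
    do_ <- dh * s$tc * s$o * (1 - s$o)
    dz <- cbind(di, df, dg, do_)
    dWx <- dWx + crossprod(s$xt, dz)
    dWh <- dWh + crossprod(s$h_prev, dz)
    db <- db + colSums(dz)
    dx[, t, ] <- tcrossprod(dz, p$Wx)
    dh_next <- tcrossprod(dz, p$Wh)
    dc_next <- dc * s$f
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

# bidirectional wrapper: params list(fwd = ..., bwd = ...); output (B, T, 2U)
.bilstm_forward <- function(x, p) {
  f <- .lstm_forward(x, p$fwd)
  xr <- x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
  b <- .lstm_forward(xr, p$bwd)
  Hb <- b$out[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
  dmf <- dim(f$out)
  H <- array(0, c(dmf[1L], dmf[2L], 2L * dmf[3L]))
  H[, , seq_len(dmf[3L])] <- f$out
  H[, , dmf[3L] + seq_len(dmf[3L])] <- Hb
  list(out = H, cache = list(f = f$cache, b = b$cache, U = dmf[3L]))
}

.bilstm_backward <- function(dH, p, cache) {
  U <- cache$U
  Tn <- dim(dH)[2L]
  dHf <- dH[, , seq_len(U), drop = FALSE]
  dHb <- dH[, rev(seq_len(Tn)), U + seq_len(U), drop = FALSE]
  gf <- .lstm_backward(dHf, p$fwd, cache$f)
  gb <- .lstm_backward(dHb, p$bwd, cache$b)
  dx <- gf$dx + gb$dx[, rev(seq_len(Tn)), , drop = FALSE]
  list(dx = dx,
       fwd = list(dWx = gf$dWx, dWh = gf$dWh, db = gf$db),
       bwd = list(dWx = gb$dWx, dWh = gb$dWh, db = gb$db))
}

# ---- softmax / sparse categorical cross-entropy -----------------------------

# logits: (n, K) -> probabilities (n, K), rows sum to 1
.softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: integer class labels in 1..K (NA = masked out); returns loss and dlogits
.softmax_xent <- function(logits, y) {
  p <- .softmax(logits)
  keep <- which(!is.na(y))
  n <- length(keep)
  if (n == 0L) stop("all labels are masked")
  eps <- 1e-12
  loss <- -mean(log(p[cbind(keep, y[keep])] + eps))
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[keep, ] <- p[keep, , drop = FALSE] / n
  dlogits[cbind(keep, y[keep])] <- dlogits[cbind(keep, y[keep])] - 1 / n
  list(loss = loss, probs = p, dlogits = dlogits)
}

# ---- 2D convolution (pair trunk) --------------------------------------------

# x: (L1, L2, C); W: (k*k*C, K); 'same' zero padding, stride 1
.conv2d_forward <- function(x, W, b, k) {
  dm <- dim(x); L1 <- dm[1L]; L2 <- dm[2L]; C <- dm[3L]
  left <- (k - 1L) %/% 2L
  xp <- array(0, c(L1 + k - 1L, L2 + k - 1L, C))
  xp[left + seq_len(L1), left + seq_len(L2), ] <- x
  M <- matrix(0, L1 * L2, k * k * C)
  col <- 0L
  for (dx_ in seq_len(k)) {
    for (dy in seq_len(k)) {
      M[, col + seq_len(C)] <-
        matrix(xp[dy:(dy + L1 - 1L), dx_:(dx_ + L2 - 1L), ], L1 * L2, C)
      col <- col + C
    }
  }
  Z <- M %*% W + rep(b, each = L1 * L2)
  list(out = array(Z, c(L1, L2, length(b))),
       cache = list(M = M, dims = dm, k = k, left = left))
}

.conv2d_backward <- function(dout, W, cache) {
  dm <- cache$dims; L1 <- dm[1L]; L2 <- dm[2L]; C <- dm[3L]
  k <- cache$k; left <- cache$left
  K <- ncol(W)
  dZ <- matrix(dout, L1 * L2, K)
  dW <- crossprod(cache$M, dZ)
  db <- colSums(dZ)
  dM <- tcrossprod(dZ, W)
  dxp <- array(0, c(L1 + k - 1L, L2 + k - 1L, C))
  col <- 0L
  for (dx_ in seq_len(k)) {
    for (dy in seq_len(k)) {
      dxp[dy:(dy + L1 - 1L), dx_:(dx_ + L2 - 1L), ] <-
        dxp[dy:(dy + L1 - 1L), dx_:(dx_ + L2 - 1L), ] +
        array(dM[, col + seq_len(C)], c(L1, L2, C))
      col <- col + C
    }
  }
  list(dx = dxp[left + seq_len(L1), left + seq_len(L2), , drop = FALSE],
       dW = dW, db = db)
}

# ---- batch normalisation (per channel over all positions) -------------------

.bn_forward <- function(x, gamma, beta, running, train,
                        momentum = 0.9, eps = 1e-5) {
  dm <- dim(x); C <- dm[length(dm)]
  n <- prod(dm) / C
  xm <- matrix(x, n, C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  xhat <- (xm - rep(mu, each = n)) / rep(sqrt(v + eps), each = n)
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = array(out, dm), running = running,
       cache = list(xhat = xhat, v = v, n = n, C = C, dm = dm, eps = eps))
}

.bn_backward <- function(dout, gamma, cache) {
  n <- cache$n; C <- cache$C
  dy <- matrix(dout, n, C)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  inv_sd <- 1 / sqrt(cache$v + cache$eps)
  dxhat <- dy * rep(gamma, each = n)
  dx <- (dxhat - rep(colMeans(dxhat), each = n) -
           cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) *
    rep(inv_sd, each = n)
  list(dx = array(dx, cache$dm), dgamma = dgamma, dbeta = dbeta)
}

# ---- outer-product pair expansion -------------------------------------------

#' Outer-product expansion of per-position features to pair features
#'
#' Lifts a hidden tensor H of shape (L, F, S) to the pair tensor
#' OP[i, j, f, s] = H[i, f, s] * H[j, f, s], then flattens the last two axes
#' to give an (L, L, F*S) tensor: the input of the 2D convolutional trunk
#' that predicts the contact map.  OP is symmetric in (i, j) by construction.
#'
#' @param H numeric array (L, F, S) of per-position features.
#' @return numeric array (L, L, F*S).
#' @export
outer_product_expand <- function(H) {
  H <- as.array(H)
  if (length(dim(H)) != 3L) stop("H must be an (L, F, S) array")
  L <- dim(H)[1L]; C <- dim(H)[2L] * dim(H)[3L]
  Hm <- matrix(H, L, C)
  OP <- array(0, c(L, L, C))
  for (cidx in seq_len(C)) {
    OP[, , cidx] <- tcrossprod(Hm[, cidx])
  }
  OP
}

# gradient of outer_product_expand wrt H (matrix form L x C)
.outer_product_backward <- function(dOP, Hm) {
  L <- nrow(Hm); C <- ncol(Hm)
  dH <- matrix(0, L, C)
  for (cidx in seq_len(C)) {
    G <- dOP[, , cidx]
    dH[, cidx] <- (G + t(G)) %*% Hm[, cidx]
  }
  dH
}

# ---- RMSprop ----------------------------------------------------------------

# params/grads: nested named lists of numeric arrays with identical shapes
.rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-7) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p
      out_s <- if (is.null(s)) vector("list", length(p)) else s
      for (k in seq_along(p)) {   # by index: parameter lists may be unnamed
        r <- walk(p[[k]], g[[k]], if (k <= length(out_s)) out_s[[k]] else NULL)
        out_p[[k]] <- r$p; out_s[k] <- list(r$s)
      }
      names(out_s) <- names(p)
      list(p = out_p, s = out_s)
    } else {
      if (is.null(s)) s <- 0 * p
      s <- rho * s + (1 - rho) * g^2
      list(p = p - lr * g / (sqrt(s) + eps), s = s)
    }
  }
  walk(params, grads, state)
}

# elementwise sum of two nested grad lists
.grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- .grad_add(a[[k]], b[[k]])
    a
  } else a + b
}
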