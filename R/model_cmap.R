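# The contact-map network: embedding -> column-wise conv/pool stages over the
# full-length MSA -> outer-product pair expansion -> a trunk of square 2D
# convolutions (batch-normalised, ReLU, zero-padded to preserve L x L) ->
# 2-channel softmax over contact / non-contact.  The network is fully
# convolutional in L, so one model accepts proteins of any length.

#' Build the contact-map (CMAP) network
#'
#' @param hp hyperparameters from \code{\link{cmap_hyperparams}}.
#' @param seed RNG seed for weight initialisation.
#' @return a \code{rawmsa_model} (task \code{"cmap"}).
#' @export
build_cmap_model <- function(hp, seed = 1L) {
  stopifnot(inherits(hp, "rawmsa_hyperparams"), hp$task == "cmap")
  old <- .Random.seed_save()
  set.seed(seed)
  params <- list(emb = .init_mat(26L, hp$E))
  c_in <- hp$E
  stages <- vector("list", hp$n_column_stages)
  for (s in seq_len(hp$n_column_stages)) {
    stages[[s]] <- list(W = .init_mat(hp$pool_window * c_in, hp$conv_filters),
                        b = rep(0, hp$conv_filters))
    c_in <- hp$conv_filters
  }
  params$stages <- stages
  pair_channels <- .pooled_depth(hp) * hp$conv_filters
  k <- hp$cmap_kernel
  trunk <- vector("list", hp$cmap_trunk_depth)
  bn_running <- vector("list", hp$cmap_trunk_depth)
  c_in <- pair_channels
  for (l in seq_len(hp$cmap_trunk_depth)) {
    K <- if (l == hp$cmap_trunk_depth) 2L else hp$cmap_filters
    trunk[[l]] <- list(W = .init_mat(k * k * c_in, K), b = rep(0, K))
    if (l < hp$cmap_trunk_depth) {
      trunk[[l]]$gamma <- rep(1, K)
      trunk[[l]]$beta <- rep(0, K)
      bn_running[[l]] <- list(mean = rep(0, K), var = rep(1, K))
    }
    c_in <- K
  }
  params$trunk <- trunk
  .Random.seed_restore(old)
  structure(list(task = "cmap", hp = hp, params = params,
                 bn_running = bn_running, opt_state = NULL),
            class = "rawmsa_model")
}

#' Per-position features of the CMAP front end
#'
#' Runs the embedding and the column-wise conv/pool stages on a full-length
#' MSA, returning the hidden tensor H that feeds the outer product.  Because
#' every operation acts within single alignment columns, H at position i
#' depends only on MSA column i.
#'
#' @param model a \code{rawmsa_model} with task \code{"cmap"}.
#' @param msa an \code{encoded_msa} or an integer matrix of dim (Y, L).
#' @return numeric array (L, F, S): F = pooled alignment depth, S = filters.
#' @export
cmap_front_end <- function(model, msa) {
  stopifnot(inherits(model, "rawmsa_model"), model$task == "cmap")
  .cmap_front(model, .cmap_idx(model, msa))$H
}

.cmap_idx <- function(model, msa) {
  m <- unclass(msa)
  if (!is.matrix(m)) stop("msa must be an encoded matrix (Y x L)")
  if (nrow(m) != model$hp$Y) {
    stop("encoded depth ", nrow(m), " != model depth cap ", model$hp$Y)
  }
  t(m)  # (L, Y): positions first
}

.cmap_front <- function(model, idx) {
  hp <- model$hp; p <- model$params
  e <- .emb_forward(idx, p$emb)                     # (L, Y, E)
  xc <- e
  stage_caches <- vector("list", length(p$stages))
  for (s in seq_along(p$stages)) {
    r <- .colconv_forward(xc, p$stages[[s]]$W, p$stages[[s]]$b,
                          k = hp$pool_window, pool = hp$pool_window)
    stage_caches[[s]] <- r$cache
    xc <- r$out
  }
  list(H = xc, idx = idx, stage_caches = stage_caches)
}

.cmap_forward <- function(model, idx, train = FALSE) {
  hp <- model$hp; p <- model$params
  fe <- .cmap_front(model, idx)
  H <- fe$H
  L <- dim(H)[1L]; C <- dim(H)[2L] * dim(H)[3L]
  Hm <- matrix(H, L, C)
  x <- outer_product_expand(H)
  trunk_caches <- vector("list", length(p$trunk))
  bn_running <- model$bn_running
  for (l in seq_along(p$trunk)) {
    cv <- .conv2d_forward(x, p$trunk[[l]]$W, p$trunk[[l]]$b, hp$cmap_kernel)
    if (l < length(p$trunk)) {
      bn <- .bn_forward(cv$out, p$trunk[[l]]$gamma, p$trunk[[l]]$beta,
                        bn_running[[l]], train)
      bn_running[[l]] <- bn$running
      relu_in <- bn$out
      x <- pmax(relu_in, 0)
      trunk_caches[[l]] <- list(conv = cv$cache, bn = bn$cache,
                                relu_in = relu_in)
    } else {
      x <- cv$out
      trunk_caches[[l]] <- list(conv = cv$cache)
    }
  }
  logits <- matrix(x, L * L, 2L)
  list(logits = logits, L = L,
       cache = list(fe = fe, Hm = Hm, Hdim = dim(H),
                    trunk_caches = trunk_caches),
       bn_running = bn_running)
}

.cmap_backward <- function(model, cache, dlogits) {
  hp <- model$hp; p <- model$params
  L <- nrow(cache$Hm)
  g <- list(trunk = vector("list", length(p$trunk)))
  dx <- array(dlogits, c(L, L, 2L))
  for (l in rev(seq_along(p$trunk))) {
    tc <- cache$trunk_caches[[l]]
    if (l < length(p$trunk)) {
      dx <- dx * (tc$relu_in > 0)
      bnb <- .bn_backward(dx, p$trunk[[l]]$gamma, tc$bn)
      cvb <- .conv2d_backward(bnb$dx, p$trunk[[l]]$W, tc$conv)
      g$trunk[[l]] <- list(W = cvb$dW, b = cvb$db,
                           gamma = bnb$dgamma, beta = bnb$dbeta)
    } else {
      cvb <- .conv2d_backward(dx, p$trunk[[l]]$W, tc$conv)
      g$trunk[[l]] <- list(W = cvb$dW, b = cvb$db)
    }
    dx <- cvb$dx
  }
  dHm <- .outer_product_backward(dx, cache$Hm)
  dxc <- array(dHm, cache$Hdim)
  g$stages <- vector("list", length(p$stages))
  for (s in rev(seq_along(p$stages))) {
    r <- .colconv_backward(dxc, p$stages[[s]]$W, cache$fe$stage_caches[[s]])
    g$stages[[s]] <- list(W = r$dW, b = r$db)
    dxc <- r$dx
  }
  g$emb <- .emb_backward(cache$fe$idx, dxc, 26L, hp$E)
  g[c("emb", "stages", "trunk")]
}

#' Predict a contact probability map
#'
#' @param model a trained \code{rawmsa_model} with task \code{"cmap"}.
#' @param msa an \code{encoded_msa} (or Y x L integer matrix).
#' @param symmetrize if TRUE, return (P + t(P)) / 2; the raw network output
#'   is not exactly symmetric because the trunk convolutions are free to
#'   break pair symmetry.
#' @return numeric L x L matrix of contact probabilities.
#' @export
predict_contacts <- function(model, msa, symmetrize = FALSE) {
  stopifnot(inherits(model, "rawmsa_model"), model$task == "cmap")
  fw <- .cmap_forward(model, .cmap_idx(model, msa), train = FALSE)
  P <- matrix(.softmax(fw$logits)[, 2L], fw$L, fw$L)
  if (symmetrize) P <- (P + t(P)) / 2
  P
}
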