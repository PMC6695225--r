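# The per-residue network: embedding -> column-wise conv/pool stage(s) ->
# stacked bidirectional LSTMs -> three fully connected layers -> softmax.
# One window of the MSA (width x Y) predicts the class of its central
# master residue; a protein contributes L windows, trained as one batch.

#' Build the per-residue SS/RSA network
#'
#' @param hp hyperparameters from \code{\link{ss_rsa_hyperparams}}.
#' @param seed RNG seed for weight initialisation.
#' @return a \code{rawmsa_model} (task \code{"ss_rsa"}).
#' @export
build_ss_rsa_model <- function(hp, seed = 1L) {
  stopifnot(inherits(hp, "rawmsa_hyperparams"), hp$task == "ss_rsa")
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
  d_in <- .pooled_depth(hp) * hp$conv_filters
  lstm <- vector("list", hp$lstm_layers)
  for (l in seq_len(hp$lstm_layers)) {
    lstm[[l]] <- list(fwd = .lstm_init(d_in, hp$lstm_units),
                      bwd = .lstm_init(d_in, hp$lstm_units))
    d_in <- 2L * hp$lstm_units
  }
  params$lstm <- lstm
  flat <- hp$window * 2L * hp$lstm_units
  params$fc <- list(
    l1 = list(W = .init_mat(flat, hp$fc_units[1L]), b = rep(0, hp$fc_units[1L])),
    l2 = list(W = .init_mat(hp$fc_units[1L], hp$fc_units[2L]),
              b = rep(0, hp$fc_units[2L])),
    out = list(W = .init_mat(hp$fc_units[2L], hp$n_classes),
               b = rep(0, hp$n_classes))
  )
  .Random.seed_restore(old)
  structure(list(task = "ss_rsa", hp = hp, params = params, opt_state = NULL),
            class = "rawmsa_model")
}

#' @export
print.rawmsa_model <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "unlist")))
  cat(sprintf("rawmsa_model (%s): E=%d Y=%d, %d parameters\n",
              x$task, x$hp$E, x$hp$Y, np))
  invisible(x)
}

# forward pass; x: integer array (B, window, Y); returns logits + cache
.ss_rsa_forward <- function(model, x, train = FALSE) {
  hp <- model$hp; p <- model$params
  dm <- dim(x); B <- dm[1L]; Tw <- dm[2L]
  if (Tw != hp$window || dm[3L] != hp$Y) {
    stop("window tensor must be (batch, ", hp$window, ", ", hp$Y, ")")
  }
  e <- .emb_forward(x, p$emb)                       # (B, Tw, Y, E)
  xc <- array(e, c(B * Tw, hp$Y, hp$E))             # columns folded
  stage_caches <- vector("list", length(p$stages))
  for (s in seq_along(p$stages)) {
    r <- .colconv_forward(xc, p$stages[[s]]$W, p$stages[[s]]$b,
                          k = hp$pool_window, pool = hp$pool_window)
    stage_caches[[s]] <- r$cache
    xc <- r$out
  }
  feat_dim <- dim(xc)[2L] * dim(xc)[3L]
  h <- array(xc, c(B, Tw, feat_dim))
  lstm_caches <- vector("list", length(p$lstm))
  drop_caches <- vector("list", length(p$lstm))
  for (l in seq_along(p$lstm)) {
    r <- .bilstm_forward(h, p$lstm[[l]])
    lstm_caches[[l]] <- r$cache
    d <- .dropout_forward(r$out, hp$dropout, train)
    drop_caches[l] <- list(d$cache)   # list-assign: keeps NULL entries
    h <- d$out
  }
  flat <- matrix(h, B, Tw * dim(h)[3L])
  f1 <- .dense_forward(flat, p$fc$l1$W, p$fc$l1$b, relu = TRUE)
  d1 <- .dropout_forward(f1$out, hp$dropout, train)
  f2 <- .dense_forward(d1$out, p$fc$l2$W, p$fc$l2$b, relu = TRUE)
  d2 <- .dropout_forward(f2$out, hp$dropout, train)
  fo <- .dense_forward(d2$out, p$fc$out$W, p$fc$out$b, relu = FALSE)
  list(logits = fo$out,
       cache = list(x = x, B = B, Tw = Tw, feat_dim = feat_dim,
                    stage_caches = stage_caches, lstm_caches = lstm_caches,
                    drop_caches = drop_caches, f1 = f1$cache, d1 = d1$cache,
                    f2 = f2$cache, d2 = d2$cache, fo = fo$cache,
                    h_dim = dim(h)))
}

.ss_rsa_backward <- function(model, cache, dlogits) {
  hp <- model$hp; p <- model$params
  g <- list()
  bo <- .dense_backward(dlogits, p$fc$out$W, cache$fo)
  d2 <- .dropout_backward(bo$dx, cache$d2)
  b2 <- .dense_backward(d2, p$fc$l2$W, cache$f2)
  d1 <- .dropout_backward(b2$dx, cache$d1)
  b1 <- .dense_backward(d1, p$fc$l1$W, cache$f1)
  g$fc <- list(l1 = list(W = b1$dW, b = b1$db),
               l2 = list(W = b2$dW, b = b2$db),
               out = list(W = bo$dW, b = bo$db))
  dh <- array(b1$dx, cache$h_dim)
  g$lstm <- vector("list", length(p$lstm))
  for (l in rev(seq_along(p$lstm))) {
    dh <- .dropout_backward(dh, cache$drop_caches[[l]])
    r <- .bilstm_backward(dh, p$lstm[[l]], cache$lstm_caches[[l]])
    g$lstm[[l]] <- list(fwd = list(Wx = r$fwd$dWx, Wh = r$fwd$dWh,
                                   b = r$fwd$db),
                        bwd = list(Wx = r$bwd$dWx, Wh = r$bwd$dWh,
                                   b = r$bwd$db))
    dh <- r$dx
  }
  B <- cache$B; Tw <- cache$Tw
  dxc <- array(dh, c(B * Tw, cache$feat_dim))
  d2l <- .pooled_depth(hp)
  dxc <- array(dxc, c(B * Tw, d2l, hp$conv_filters))
  g$stages <- vector("list", length(p$stages))
  for (s in rev(seq_along(p$stages))) {
    r <- .colconv_backward(dxc, p$stages[[s]]$W, cache$stage_caches[[s]])
    g$stages[[s]] <- list(W = r$dW, b = r$db)
    dxc <- r$dx
  }
  de <- array(dxc, c(B, Tw, hp$Y, hp$E))
  g$emb <- .emb_backward(cache$x, de, 26L, hp$E)
  g[c("emb", "stages", "lstm", "fc")]
}

#' Predict per-residue class probabilities
#'
#' @param model a trained \code{rawmsa_model} with task \code{"ss_rsa"}.
#' @param msa an \code{encoded_msa} (depth must equal the model's Y), a list
#'   of windows from \code{\link{extract_windows}}, or a window tensor
#'   (B, window, Y).
#' @return numeric matrix (L, n_classes) of softmax probabilities, one row
#'   per master residue; columns named by \code{hp$class_labels} when set.
#' @export
predict_ss_rsa <- function(model, msa) {
  stopifnot(inherits(model, "rawmsa_model"), model$task == "ss_rsa")
  x <- .as_window_tensor(msa, model$hp)
  probs <- .softmax(.ss_rsa_forward(model, x, train = FALSE)$logits)
  if (!is.null(model$hp$class_labels)) colnames(probs) <- model$hp$class_labels
  probs
}

.as_window_tensor <- function(msa, hp) {
  if (inherits(msa, "encoded_msa")) {
    if (attr(msa, "Y") != hp$Y) {
      stop("encoded depth ", attr(msa, "Y"), " != model depth cap ", hp$Y)
    }
    windows_tensor(extract_windows(msa, hp$window))
  } else if (is.list(msa)) {
    windows_tensor(msa)
  } else {
    as.array(msa)
  }
}

#' Nearest residues in the learned embedding space
#'
#' Ranks all other vocabulary symbols by cosine similarity to the query
#' residue's embedding vector (self excluded, highest similarity first).
#' Useful for checking that the learned space groups chemically similar
#' amino acids.
#'
#' @param embedding a trained \code{rawmsa_model}, or an embedding matrix
#'   with 25 rows (symbols 1..25) or 26 rows (padding row 0 first).
#' @param query one-letter residue code.
#' @param k number of neighbours to return (< 25).
#' @return data.frame with columns \code{symbol} and \code{cosine}.
#' @export
embedding_similarity <- function(embedding, query, k = 5L) {
  if (inherits(embedding, "rawmsa_model")) {
    embedding <- embedding$params$emb
  }
  embedding <- as.matrix(embedding)
  if (nrow(embedding) == 26L) embedding <- embedding[-1L, , drop = FALSE]
  if (nrow(embedding) != 25L) {
    stop("embedding matrix must have 25 (or 26 incl. padding) rows")
  }
  if (k >= 25L) stop("k must be < 25")
  vocab <- residue_vocabulary()
  qi <- vocab$symbol_to_index[query]
  if (is.na(qi)) stop("unknown residue code: ", query)
  qv <- embedding[qi, ]
  others <- setdiff(seq_len(25L), qi)
  cosines <- vapply(others, function(i) {
    v <- embedding[i, ]
    den <- sqrt(sum(qv^2)) * sqrt(sum(v^2))
    if (den == 0) 0 else sum(qv * v) / den
  }, numeric(1L))
  ord <- order(-cosines)
  data.frame(symbol = vocab$index_to_symbol[others][ord],
             cosine = cosines[ord])[seq_len(k), ]
}
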