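# Training protocol: one protein per optimisation step ("one protein in each
# batch block, regardless of the size"), RMSprop, sparse categorical
# cross-entropy, a random per-protein validation split, and selection of the
# checkpoint that scores best on validation.

#' Training configuration
#'
#' @param epochs number of passes over the training proteins (the published
#'   protocol: 5 for SS/RSA, up to 200 for CMAP).
#' @param learning_rate RMSprop learning rate.
#' @param validation_fraction fraction of proteins reserved for validation.
#' @param seed RNG seed controlling the split, shuffling, dropout.
#' @param patience early-stopping patience in epochs (Inf = never stop
#'   early); validation-based stopping is the published protocol for CMAP.
#' @param select_on checkpoint-selection metric: \code{"accuracy"} (highest
#'   validation accuracy; SS/RSA protocol) or \code{"loss"} (lowest
#'   validation error; CMAP protocol).  Default \code{"auto"} picks by task.
#' @param checkpoint_dir optional directory; when set, an RDS checkpoint is
#'   written each time validation improves.
#' @param verbose print one line per epoch.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(epochs, learning_rate = 1e-3,
                         validation_fraction = 0.10, seed = 1L,
                         patience = Inf, select_on = "auto",
                         checkpoint_dir = NULL, verbose = FALSE) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  if (!select_on %in% c("auto", "accuracy", "loss")) {
    stop("select_on must be 'auto', 'accuracy' or 'loss'")
  }
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), patience = patience,
                 select_on = select_on, checkpoint_dir = checkpoint_dir,
                 verbose = verbose),
            class = "train_config")
}

#' Split protein ids into training and validation sets
#'
#' Splitting is by protein, never by window, so a protein's own windows can
#' never leak between the two sets.  The validation set has
#' \code{max(1, round(fraction * n))} proteins.
#'
#' @param samples vector of protein identifiers.
#' @param fraction validation fraction in (0, 1).
#' @param seed RNG seed; identical seeds give identical splits.
#' @return list with elements \code{train} and \code{validation}.
#' @export
split_train_validation <- function(samples, fraction = 0.10, seed = 1L) {
  if (length(samples) < 2L) stop("need at least 2 samples to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  old <- .Random.seed_save()
  set.seed(seed)
  n_val <- max(1L, round(fraction * length(samples)))
  val <- sample(samples, n_val)
  .Random.seed_restore(old)
  list(train = setdiff(samples, val), validation = val)
}

# per-protein forward + loss/accuracy; returns also dlogits & cache for
# training steps
.protein_pass <- function(model, prot, train = FALSE) {
  if (model$task == "ss_rsa") {
    fw <- .ss_rsa_forward(model, prot$x, train = train)
    y <- prot$y
  } else {
    fw <- .cmap_forward(model, .cmap_idx(model, prot$x), train = train)
    ym <- prot$y
    y <- as.integer(as.vector(unclass(ym))) + 1L  # 0/1 -> class 1/2, NA kept
  }
  sx <- .softmax_xent(fw$logits, y)
  keep <- !is.na(y)
  pred <- max.col(sx$probs[keep, , drop = FALSE], ties.method = "first")
  list(fw = fw, loss = sx$loss, dlogits = sx$dlogits,
       n = sum(keep), correct = sum(pred == y[keep]))
}

.check_labels <- function(model, data) {
  for (nm in names(data)) {
    prot <- data[[nm]]
    if (model$task == "ss_rsa") {
      y <- prot$y
      if (length(y) == 0L) stop("protein ", nm, " has no labels")
      if (any(!is.na(y) & (y < 1L | y > model$hp$n_classes))) {
        stop("protein ", nm, ": labels must lie in 1..", model$hp$n_classes)
      }
    } else {
      y <- unclass(prot$y)
      if (any(!is.na(y) & !y %in% c(0L, 1L))) {
        stop("protein ", nm, ": contact maps must be 0/1 (NA = masked)")
      }
    }
  }
}

#' Train a model with the one-protein-per-batch protocol
#'
#' Each optimisation step consumes exactly one protein: all of its windows
#' (SS/RSA) or its full contact map (CMAP).  A random fraction of the
#' proteins is held out for validation; after every epoch the validation
#' loss and accuracy are recorded and the parameters are checkpointed
#' whenever the selection metric improves.  The returned model carries the
#' best checkpoint's weights.
#'
#' @param model a \code{rawmsa_model} from \code{\link{build_ss_rsa_model}}
#'   or \code{\link{build_cmap_model}}.
#' @param data named list of proteins; each element is
#'   \code{list(x = ..., y = ...)}: a window tensor (B, window, Y) with
#'   integer labels for SS/RSA, or an encoded MSA with an L x L 0/1 map
#'   (NA = masked) for CMAP.
#' @param cfg a \code{\link{train_config}}.
#' @return list of class \code{rawmsa_training} with elements \code{model}
#'   (best checkpoint), \code{history} (per-epoch data.frame) and
#'   \code{best_epoch}.
#' @export
train_model <- function(model, data, cfg) {
  stopifnot(inherits(model, "rawmsa_model"), inherits(cfg, "train_config"))
  if (length(data) == 0L) stop("empty training data")
  if (is.null(names(data))) names(data) <- paste0("prot", seq_along(data))
  .check_labels(model, data)
  select_on <- if (cfg$select_on == "auto") {
    if (model$task == "cmap") "loss" else "accuracy"
  } else cfg$select_on

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  split <- split_train_validation(names(data), cfg$validation_fraction,
                                  seed = cfg$seed)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric(),
                     checkpoint = logical())
  best_metric <- if (select_on == "loss") Inf else -Inf
  best_params <- model$params
  best_bn <- model$bn_running
  since_improve <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    order_ids <- sample(split$train)
    train_losses <- numeric(length(order_ids))
    for (k in seq_along(order_ids)) {
      prot <- data[[order_ids[k]]]
      pass <- .protein_pass(model, prot, train = TRUE)
      train_losses[k] <- pass$loss
      grads <- if (model$task == "ss_rsa") {
        .ss_rsa_backward(model, pass$fw$cache, pass$dlogits)
      } else {
        model$bn_running <- pass$fw$bn_running
        .cmap_backward(model, pass$fw$cache, pass$dlogits)
      }
      upd <- .rmsprop_step(model$params, grads, model$opt_state,
                           lr = cfg$learning_rate)
      model$params <- upd$p
      model$opt_state <- upd$s
    }
    val <- lapply(split$validation, function(id) {
      .protein_pass(model, data[[id]], train = FALSE)
    })
    val_loss <- mean(vapply(val, `[[`, numeric(1L), "loss"))
    val_acc <- sum(vapply(val, `[[`, numeric(1L), "correct")) /
      sum(vapply(val, `[[`, numeric(1L), "n"))
    metric <- if (select_on == "loss") val_loss else val_acc
    improved <- if (select_on == "loss") metric < best_metric
                else metric > best_metric
    if (improved) {
      best_metric <- metric
      best_params <- model$params
      best_bn <- model$bn_running
      since_improve <- 0L
      if (!is.null(cfg$checkpoint_dir)) {
        dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        ckpt <- model
        save_checkpoint(ckpt, file.path(cfg$checkpoint_dir,
                                        sprintf("epoch_%03d.rds", epoch)))
      }
    } else {
      since_improve <- since_improve + 1L
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(train_losses),
                                   val_loss = val_loss,
                                   val_accuracy = val_acc,
                                   checkpoint = improved))
    if (cfg$verbose) {
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val acc %.4f%s",
                      epoch, mean(train_losses), val_loss, val_acc,
                      if (improved) "  *" else ""))
    }
    if (since_improve >= cfg$patience) break
  }
  attr(hist, "select_on") <- select_on
  class(hist) <- c("train_history", class(hist))
  model$params <- best_params
  model$bn_running <- best_bn
  structure(list(model = model, history = hist,
                 best_epoch = select_best_model(hist)),
            class = "rawmsa_training")
}

#' Select the best epoch from a training history
#'
#' Returns the epoch with the highest validation accuracy (or, when the
#' history was recorded under \code{select_on = "loss"}, the lowest
#' validation loss); ties go to the earliest epoch.
#'
#' @param history a \code{train_history} data.frame from
#'   \code{\link{train_model}}, with columns \code{epoch},
#'   \code{val_accuracy} and \code{val_loss}.
#' @return integer epoch number.
#' @export
select_best_model <- function(history) {
  if (nrow(history) == 0L) stop("empty training history")
  select_on <- attr(history, "select_on") %||% "accuracy"
  metric <- if (select_on == "loss") -history$val_loss else history$val_accuracy
  history$epoch[which.max(metric)]  # which.max takes the first tie
}

#' Save a model checkpoint (weights + hyperparameters)
#' @param model a \code{rawmsa_model}.
#' @param path output .rds path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "rawmsa_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model checkpoint written by \code{\link{save_checkpoint}}
#' @param path checkpoint path.
#' @return a \code{rawmsa_model}.
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rawmsa_model")) stop("not a rawmsa checkpoint: ", path)
  model
}
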