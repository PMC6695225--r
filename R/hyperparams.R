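# Hyperparameter containers for the two architectures.

#' Hyperparameters for the per-residue (SS/RSA) network
#'
#' @param E embedding dimension (the published models use 10-30).
#' @param Y alignment depth cap.
#' @param window sliding-window width over the master sequence (odd).
#' @param pool_window column conv/pool window W along the depth axis;
#'   defaults to E.
#' @param conv_filters filters per column stage; defaults to E.
#' @param n_column_stages number of column conv/pool stages (1 here).
#' @param lstm_units hidden units per LSTM direction (350 at full scale).
#' @param lstm_layers number of stacked bidirectional LSTM layers.
#' @param fc_units sizes of the two hidden fully-connected layers.
#' @param dropout dropout fraction after each recurrent/dense layer.
#' @param n_classes 3 (SS), 4 or 2 (RSA).
#' @param class_labels optional label names attached to predictions.
#' @return list of class \code{rawmsa_hyperparams}.
#' @export
ss_rsa_hyperparams <- function(E = 10L, Y = 500L, window = 31L,
                               pool_window = E, conv_filters = E,
                               n_column_stages = 1L, lstm_units = 350L,
                               lstm_layers = 2L, fc_units = c(200L, 200L),
                               dropout = 0.5, n_classes = 3L,
                               class_labels = NULL) {
  hp <- list(task = "ss_rsa", E = as.integer(E), Y = as.integer(Y),
             window = as.integer(window), pool_window = as.integer(pool_window),
             conv_filters = as.integer(conv_filters),
             n_column_stages = as.integer(n_column_stages),
             lstm_units = as.integer(lstm_units),
             lstm_layers = as.integer(lstm_layers),
             fc_units = as.integer(fc_units), dropout = dropout,
             n_classes = as.integer(n_classes), class_labels = class_labels)
  .validate_hyperparams(hp)
  structure(hp, class = "rawmsa_hyperparams")
}

#' Hyperparameters for the contact-map (CMAP) network
#'
#' @param E embedding dimension.
#' @param Y alignment depth cap.
#' @param pool_window column conv/pool window along the depth axis.
#' @param conv_filters filters per column stage; defaults to E.
#' @param n_column_stages number of column conv/pool stages (up to 6).
#' @param cmap_trunk_depth number of square-convolution layers after the
#'   outer product (published models use 6-20).
#' @param cmap_kernel square kernel size (3, 5 or 10).
#' @param cmap_filters filters per trunk layer (10-50 at full scale).
#' @return list of class \code{rawmsa_hyperparams}.
#' @export
cmap_hyperparams <- function(E = 10L, Y = 100L, pool_window = E,
                             conv_filters = E, n_column_stages = 2L,
                             cmap_trunk_depth = 6L, cmap_kernel = 3L,
                             cmap_filters = 20L) {
  hp <- list(task = "cmap", E = as.integer(E), Y = as.integer(Y),
             pool_window = as.integer(pool_window),
             conv_filters = as.integer(conv_filters),
             n_column_stages = as.integer(n_column_stages),
             cmap_trunk_depth = as.integer(cmap_trunk_depth),
             cmap_kernel = as.integer(cmap_kernel),
             cmap_filters = as.integer(cmap_filters),
             n_classes = 2L, class_labels = c("noncontact", "contact"))
  .validate_hyperparams(hp)
  structure(hp, class = "rawmsa_hyperparams")
}

.validate_hyperparams <- function(hp) {
  if (hp$E < 1L) stop("embedding size E must be >= 1")
  if (hp$Y < 1L) stop("depth cap Y must be >= 1")
  if (hp$pool_window < 1L) stop("pool_window must be >= 1")
  if (hp$conv_filters < 1L) stop("conv_filters must be >= 1")
  if (hp$n_column_stages < 1L) stop("n_column_stages must be >= 1")
  if (hp$task == "ss_rsa") {
    if (hp$window %% 2L == 0L) stop("window width must be odd")
    if (!hp$n_classes %in% c(2L, 3L, 4L)) {
      stop("n_classes must be 2, 3 or 4")
    }
    if (hp$lstm_units < 1L || hp$lstm_layers < 1L) {
      stop("lstm_units and lstm_layers must be positive")
    }
    if (hp$dropout < 0 || hp$dropout >= 1) stop("dropout must be in [0, 1)")
    if (any(hp$fc_units < 1L)) stop("fc_units must be positive")
  } else {
    if (hp$cmap_trunk_depth < 1L) stop("cmap_trunk_depth must be >= 1")
    if (hp$cmap_kernel < 1L) stop("cmap_kernel must be >= 1")
    if (hp$cmap_filters < 1L) stop("cmap_filters must be >= 1")
  }
  # pooled depth after the column stages must stay >= 1
  d <- hp$Y
  for (s in seq_len(hp$n_column_stages)) d <- d %/% hp$pool_window
  if (d < 1L) {
    stop("depth cap Y = ", hp$Y, " is exhausted by ", hp$n_column_stages,
         " pooling stage(s) of window ", hp$pool_window)
  }
  invisible(hp)
}

# pooled alignment depth after all column stages
.pooled_depth <- function(hp) {
  d <- hp$Y
  for (s in seq_len(hp$n_column_stages)) d <- d %/% hp$pool_window
  d
}

#' Write hyperparameters to a JSON config file
#' @param hp a \code{rawmsa_hyperparams} object.
#' @param path output path.
#' @export
write_hyperparams <- function(hp, path) {
  jsonlite::write_json(unclass(hp), path, auto_unbox = TRUE, pretty = TRUE)
}

#' Read hyperparameters from a JSON config file
#' @param path config path written by \code{\link{write_hyperparams}}.
#' @return a \code{rawmsa_hyperparams} object.
#' @export
read_hyperparams <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(cfg$task, "cmap")) {
    do.call(cmap_hyperparams, cfg[setdiff(names(cfg),
                                          c("task", "n_classes",
                                            "class_labels"))])
  } else {
    do.call(ss_rsa_hyperparams, cfg[setdiff(names(cfg), "task")])
  }
}
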