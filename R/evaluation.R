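# Scoring: multiclass per-residue accuracy (Q3/Q4/Q2) and CASP-style
# top-L/5 long-range contact precision, plus equal-weight dataset averages.

#' Multiclass accuracy over unmasked positions
#'
#' @param pred predicted class labels (any comparable vector).
#' @param truth true class labels, same length.
#' @param mask optional logical vector, TRUE = exclude the position.
#' @return fraction correct in [0, 1].
#' @export
multiclass_accuracy <- function(pred, truth, mask = NULL) {
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ: ", length(pred), " vs ",
         length(truth))
  }
  keep <- rep(TRUE, length(pred))
  if (!is.null(mask)) keep <- keep & !mask
  keep <- keep & !is.na(truth)
  if (!any(keep)) stop("all positions are masked")
  mean(pred[keep] == truth[keep])
}

#' Precision of the top L/5 predicted long-range contacts
#'
#' Eligible pairs are upper-triangle pairs with sequence separation > 23
#' whose truth is unmasked.  They are ranked by predicted probability
#' (descending; ties by ascending (i, j)), the top floor(L/5) (minimum 1,
#' at most the number of eligible pairs) are selected, and the precision is
#' the fraction of selected pairs that are true contacts.
#'
#' @param pred L x L numeric probability matrix.
#' @param truth L x L 0/1 matrix (a \code{contact_map}; NA = masked).
#' @param min_sep_over long-range threshold: pairs need |i - j| > this.
#' @param top_fraction selects floor(L / top_fraction) pairs (default 5).
#' @return precision in [0, 1].
#' @export
top_l5_long_range_precision <- function(pred, truth, min_sep_over = 23L,
                                        top_fraction = 5L) {
  pred <- unclass(pred); truth <- unclass(truth)
  if (!all(dim(pred) == dim(truth))) {
    stop("pred and truth must both be L x L with the same L")
  }
  L <- nrow(pred)
  pairs <- long_range_pairs(L, min_sep_over)
  if (nrow(pairs) == 0L) stop("no long-range pairs at L = ", L)
  tvals <- truth[pairs]
  keep <- !is.na(tvals)
  pairs <- pairs[keep, , drop = FALSE]
  tvals <- tvals[keep]
  if (length(tvals) == 0L) stop("all long-range pairs are masked")
  scores <- pred[pairs]
  ord <- order(-scores, pairs[, 1L], pairs[, 2L])
  n_sel <- min(max(1L, L %/% top_fraction), length(ord))
  sel <- ord[seq_len(n_sel)]
  sum(tvals[sel]) / n_sel
}

#' Evaluate a set of targets and average the per-target metric
#'
#' The dataset-level number is the unweighted mean of the per-target
#' metrics (every target counts equally, regardless of its length).
#'
#' @param predictions named list of per-target predictions.
#' @param truths named list of per-target truths; every truth target must
#'   have a prediction.
#' @param metric function(pred, truth) returning one number, e.g.
#'   \code{\link{multiclass_accuracy}} or
#'   \code{\link{top_l5_long_range_precision}}.
#' @return an \code{evaluation_report}: list with \code{per_target}
#'   (data.frame target/value) and \code{average}.
#' @export
evaluate_dataset <- function(predictions, truths, metric) {
  missing_ids <- setdiff(names(truths), names(predictions))
  if (length(missing_ids) > 0L) {
    stop("missing predictions for target(s): ",
         paste(missing_ids, collapse = ", "))
  }
  vals <- vapply(names(truths), function(id) {
    metric(predictions[[id]], truths[[id]])
  }, numeric(1L))
  structure(list(per_target = data.frame(target = names(truths),
                                         value = unname(vals)),
                 average = mean(vals)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d targets, average = %.4f\n",
              nrow(x$per_target), x$average))
  invisible(x)
}

#' Write an evaluation report as a TSV table
#' @param report an \code{evaluation_report}.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  df <- rbind(report$per_target,
              data.frame(target = "AVERAGE", value = report$average))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
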