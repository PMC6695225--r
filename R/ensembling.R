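# Softmax-averaging ensembles: class probabilities from several trained
# models (and, for contacts, several alignment sources) are averaged and the
# final class is the one with the highest mean probability.

#' Average class-probability distributions
#'
#' @param distributions list of simplex vectors of equal length (or a matrix
#'   with one distribution per row).
#' @param tolerance each input must sum to 1 within this tolerance.
#' @return list with \code{mean} (averaged simplex vector) and \code{class}
#'   (argmax index, ties broken by the lowest class index).
#' @export
ensemble_average <- function(distributions, tolerance = 1e-4) {
  if (is.matrix(distributions)) {
    distributions <- lapply(seq_len(nrow(distributions)),
                            function(r) distributions[r, ])
  }
  if (length(distributions) == 0L) stop("no distributions to ensemble")
  len <- vapply(distributions, length, integer(1L))
  if (length(unique(len)) != 1L) {
    stop("distributions have unequal lengths: ",
         paste(unique(len), collapse = ", "))
  }
  for (d in distributions) {
    if (any(d < -tolerance) || abs(sum(d) - 1) > tolerance) {
      stop("input is not a probability distribution (sum = ", sum(d), ")")
    }
  }
  m <- Reduce(`+`, distributions) / length(distributions)
  list(mean = m, class = which.max(m))
}

#' Ensemble per-residue probability matrices
#'
#' Averages the (L x K) softmax outputs of several models row-wise and
#' returns the winning class per residue.
#'
#' @param members list of numeric matrices of identical dim (L, K).
#' @return list with \code{probs} (averaged matrix) and \code{classes}
#'   (integer vector of argmax classes, first index on ties).
#' @export
ensemble_predictions <- function(members) {
  if (length(members) == 0L) stop("no members to ensemble")
  dims <- lapply(members, dim)
  if (length(unique(dims)) != 1L) stop("member outputs differ in shape")
  probs <- Reduce(`+`, members) / length(members)
  list(probs = probs, classes = max.col(probs, ties.method = "first"))
}

#' Ensemble contact-map predictions over models and alignment sources
#'
#' Every model predicts once per alignment source (e.g. alignments from two
#' different aligners); the per-pair contact probabilities are averaged over
#' all model x alignment combinations and the final map is symmetrized as
#' (P[i,j] + P[j,i]) / 2.  All alignments must describe the same master
#' sequence; a length or sequence mismatch fails loudly.
#'
#' @param members list of trained CMAP \code{rawmsa_model}s (or paths to
#'   checkpoints saved with \code{\link{save_checkpoint}}).
#' @param alignments list of \code{\link{raw_alignment}}s for the target
#'   (1 or 2 sources typically).
#' @return a \code{contact_prediction}: symmetric L x L probability matrix.
#' @export
predict_contacts_ensemble <- function(members, alignments) {
  if (length(members) == 0L) stop("no ensemble members")
  if (length(alignments) == 0L) stop("no alignments")
  members <- lapply(members, function(m) {
    if (is.character(m)) load_checkpoint(m) else m
  })
  masters <- vapply(alignments, function(a) a$sequences[1L], character(1L))
  if (length(unique(masters)) != 1L) {
    stop("alignment sources disagree on the master sequence")
  }
  maps <- list()
  for (m in members) {
    if (m$task != "cmap") stop("ensemble member is not a CMAP model")
    for (a in alignments) {
      enc <- encode_msa(a, depth_cap = m$hp$Y)
      maps <- c(maps, list(predict_contacts(m, enc, symmetrize = FALSE)))
    }
  }
  P <- Reduce(`+`, maps) / length(maps)
  P <- (P + t(P)) / 2
  structure(P, class = c("contact_prediction", class(P)))
}

#' Write a contact prediction in CASP RR text format
#'
#' One line per upper-triangle pair: \code{i j 0 8 probability}, sorted by
#' probability descending.
#'
#' @param probmap L x L numeric probability matrix.
#' @param path output path.
#' @param min_separation only write pairs with |i - j| >= this (default 1,
#'   i.e. all off-diagonal pairs).
#' @export
write_rr <- function(probmap, path, min_separation = 1L) {
  L <- nrow(probmap)
  idx <- which(upper.tri(probmap), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] >= min_separation, , drop = FALSE]
  p <- probmap[idx]
  ord <- order(-p, idx[, 1L], idx[, 2L])
  lines <- sprintf("%d %d 0 8 %.6f", idx[ord, 1L], idx[ord, 2L], p[ord])
  writeLines(lines, path)
}

#' Read a CASP RR contact file into a dense probability matrix
#'
#' @param path RR file with lines \code{i j d1 d2 probability}.
#' @param L protein length.
#' @return symmetric L x L numeric matrix (unlisted pairs get 0).
#' @export
read_rr <- function(path, L) {
  tb <- utils::read.table(path)
  if (ncol(tb) < 5L) stop("RR file must have 5 columns: i j d1 d2 prob")
  P <- matrix(0, L, L)
  P[cbind(tb[[1L]], tb[[2L]])] <- tb[[5L]]
  P[cbind(tb[[2L]], tb[[1L]])] <- tb[[5L]]
  P
}
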