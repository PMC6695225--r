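# Homolog-safe dataset splitting: chains are assigned to cross-validation
# folds whole-superfamily at a time, so no structural superfamily ever
# contributes chains to more than one fold.

#' Keep only chains assigned to exactly one superfamily
#'
#' Chains related to more than one superfamily are ambiguous for
#' superfamily-disjoint splitting and are removed; chains with no
#' assignment are removed in the same spirit.
#'
#' @param assignments either a data.frame with columns \code{chain} and
#'   \code{superfamily} (one row per assignment), or a named list mapping
#'   chain id to a character vector of superfamily ids.
#' @return data.frame with columns \code{chain}, \code{superfamily} for the
#'   retained chains (one row each).
#' @export
filter_single_superfamily <- function(assignments) {
  if (is.data.frame(assignments)) {
    if (nrow(assignments) == 0L) {
      return(data.frame(chain = character(), superfamily = character()))
    }
    sets <- split(unique(assignments[c("chain", "superfamily")])$superfamily,
                  unique(assignments[c("chain", "superfamily")])$chain)
  } else {
    sets <- lapply(assignments, unique)
  }
  keep <- vapply(sets, length, integer(1L)) == 1L
  data.frame(chain = names(sets)[keep],
             superfamily = unlist(sets[keep], use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Split chains into superfamily-disjoint folds
#'
#' Superfamilies are assigned whole to folds by greedy size balancing:
#' largest superfamily first, into the currently smallest fold.  The seed
#' shuffles the order among equal-sized superfamilies, so different seeds
#' yield different (but always superfamily-disjoint) splits.
#'
#' @param chains data.frame with columns \code{chain} and \code{superfamily}
#'   (one superfamily per chain, e.g. the output of
#'   \code{\link{filter_single_superfamily}}).
#' @param k number of folds (default 5).
#' @param seed RNG seed for tie shuffling.
#' @return a \code{fold_split}: named integer vector (chain -> fold in 1..k)
#'   with attribute \code{superfamily_fold}.
#' @export
split_by_superfamily <- function(chains, k = 5L, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (nrow(chains) == 0L) {
    return(structure(integer(0L), class = "fold_split"))
  }
  sizes <- table(chains$superfamily)
  if (length(sizes) < k) {
    warning("only ", length(sizes), " superfamilies for ", k,
            " folds; some folds will be empty")
  }
  old <- .Random.seed_save()
  set.seed(seed)
  ord <- sample(seq_along(sizes))             # shuffle, then stable sort:
  ord <- ord[order(-as.integer(sizes)[ord])]  # ties stay in shuffled order
  .Random.seed_restore(old)
  fold_of_sf <- stats::setNames(integer(length(sizes)), names(sizes))
  fold_sizes <- integer(k)
  for (s in ord) {
    target <- which.min(fold_sizes)           # lowest index on ties
    fold_of_sf[s] <- target
    fold_sizes[target] <- fold_sizes[target] + as.integer(sizes[s])
  }
  out <- fold_of_sf[chains$superfamily]
  names(out) <- chains$chain
  structure(out, superfamily_fold = fold_of_sf, class = "fold_split")
}

#' Read a chain-to-superfamily table
#'
#' Tab-separated file with two columns: chain id, superfamily id (multiple
#' rows per chain allowed).  Lines starting with \code{#} are skipped.
#'
#' @param path input path.
#' @return data.frame with columns \code{chain} and \code{superfamily}.
#' @export
read_superfamily_table <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("chain", "superfamily"),
                          colClasses = "character")
  tb
}

#' Write fold membership lists
#'
#' @param split a \code{fold_split}.
#' @param path output path (TSV: chain, fold).
#' @export
write_fold_split <- function(split, path) {
  utils::write.table(data.frame(chain = names(split),
                                fold = as.integer(split)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
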