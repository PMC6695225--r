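#' Residue vocabulary for integer-coding alignments
#'
#' Alignment symbols are mapped to the integers 1..25: the 20 standard amino
#' acids in alphabetical one-letter order (A, C, D, E, F, G, H, I, K, L, M, N,
#' P, Q, R, S, T, V, W, Y -> 1..20), then the non-standard letters B = 21,
#' U = 22, Z = 23, X = 24, and the gap character \code{"-"} = 25.  The index 0
#' is never assigned: it is reserved for zero-padding, so real residues can
#' never be confused with padding by the network.  Letters outside this set
#' (J, O, \code{*}, \code{.}) collapse to X.
#'
#' @return An object of class \code{residue_vocabulary}: a list with
#'   \code{symbol_to_index} (named integer vector), \code{index_to_symbol}
#'   (character vector of length 25), \code{unknown_symbol} (\code{"X"}) and
#'   \code{gap_index}.
#' @examples
#' v <- residue_vocabulary()
#' v$symbol_to_index[c("A", "X", "-")]
#' @export
residue_vocabulary <- function() {
  symbols <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y",
               "B", "U", "Z", "X", "-")
  idx <- seq_along(symbols)
  names(idx) <- symbols
  structure(
    list(symbol_to_index = idx,
         index_to_symbol = symbols,
         unknown_symbol  = "X",
         gap_index       = idx[["-"]]),
    class = "residue_vocabulary"
  )
}

#' Encode a character vector of residue symbols to integers
#'
#' Unknown letters collapse to the vocabulary's unknown symbol (X).
#'
#' @param symbols character vector of single-character residue symbols.
#' @param vocab a \code{\link{residue_vocabulary}}.
#' @return integer vector in 1..25.
#' @export
encode_symbols <- function(symbols, vocab = residue_vocabulary()) {
  idx <- vocab$symbol_to_index[symbols]
  unknown <- is.na(idx)
  if (any(unknown)) {
    idx[unknown] <- vocab$symbol_to_index[[vocab$unknown_symbol]]
  }
  unname(as.integer(idx))
}

#' Decode integer codes back to residue symbols
#'
#' @param indices integer vector in 1..25 (0 is padding and decodes to "").
#' @param vocab a \code{\link{residue_vocabulary}}.
#' @return character vector of symbols.
#' @export
decode_symbols <- function(indices, vocab = residue_vocabulary()) {
  if (any(indices < 0L | indices > 25L)) {
    stop("residue indices must lie in 0..25")
  }
  out <- character(length(indices))
  nonpad <- indices > 0L
  out[nonpad] <- vocab$index_to_symbol[indices[nonpad]]
  out
}

#' Theoretical maximum accessible surface areas
#'
#' Per-residue theoretical MaxASA values (square Angstrom) used to normalise
#' DSSP absolute accessibilities into relative solvent accessibility.  The
#' defaults are the theoretical maxima of Tien et al. (2013); the table is
#' configuration, so callers may supply their own values.
#'
#' @return named numeric vector over the 20 standard one-letter codes.
#' @export
max_asa_table <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167,
    Q = 225, E = 223, G = 104, H = 224, I = 197,
    L = 201, K = 236, M = 224, F = 240, P = 159,
    S = 155, T = 172, W = 285, Y = 263, V = 174)
}
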