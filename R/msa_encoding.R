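# ---- raw alignments ---------------------------------------------------------

#' Construct a raw alignment
#'
#' A raw alignment is a set of equal-length aligned sequences whose first row
#' is the target ("master") sequence.  Columns where the master carries a gap
#' are removed, so the alignment width always equals the master length L and
#' every per-residue quantity can be indexed by master position.
#'
#' @param sequences character vector of aligned sequences (first = master).
#' @param ids optional record identifiers.
#' @return an object of class \code{raw_alignment} with elements
#'   \code{sequences}, \code{ids}, \code{L} (master length) and \code{N}
#'   (number of sequences).
#' @export
raw_alignment <- function(sequences, ids = NULL) {
  if (length(sequences) == 0L) stop("no sequences")
  sequences <- unname(toupper(sequences))
  sequences <- gsub(".", "-", sequences, fixed = TRUE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequences have unequal lengths")
  }
  bad <- grepl("[^A-Z-]", sequences)
  if (any(bad)) {
    stop("illegal characters in aligned sequences (record ",
         which(bad)[1L], ")")
  }
  # drop columns where the master is gapped so that width == L
  master_chars <- strsplit(sequences[1L], "")[[1L]]
  keep <- master_chars != "-"
  if (!all(keep)) {
    sequences <- vapply(strsplit(sequences, ""), function(ch) {
      paste0(ch[keep], collapse = "")
    }, character(1L))
  }
  if (nchar(sequences[1L]) == 0L) stop("master sequence is all gaps")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  structure(
    list(sequences = sequences, ids = ids,
         L = nchar(sequences[1L]), N = length(sequences)),
    class = "raw_alignment"
  )
}

#' @export
print.raw_alignment <- function(x, ...) {
  cat(sprintf("raw_alignment: %d sequences, master length %d\n", x$N, x$L))
  invisible(x)
}

#' Read an alignment from FASTA or A3M
#'
#' The first record is taken as the master sequence.  Flat aligned FASTA is
#' parsed case-insensitively; in A3M, lowercase letters mark insertion states
#' relative to the master and are removed (see \code{\link{flatten_a3m}})
#' before the records are assembled into a \code{\link{raw_alignment}}.
#'
#' @param path path to the alignment file.
#' @param format \code{"fasta"} (flat, pre-aligned) or \code{"a3m"}.
#' @return a \code{\link{raw_alignment}}.
#' @export
read_alignment <- function(path, format = c("fasta", "a3m")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file does not exist: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  seqs <- as.character(set)
  ids <- names(set)
  if (format == "a3m") {
    flatten_a3m(seqs, ids = ids)
  } else {
    raw_alignment(seqs, ids = ids)
  }
}

#' Flatten A3M records into a raw alignment
#'
#' In A3M, lowercase letters are insertions relative to the master and do not
#' occupy master-indexed columns; deleting them from every record leaves a
#' flat alignment of the master's length.
#'
#' @param records character vector of A3M sequence strings, master first.
#' @param ids optional record identifiers.
#' @return a \code{\link{raw_alignment}}.
#' @export
flatten_a3m <- function(records, ids = NULL) {
  if (length(records) == 0L) stop("no sequences")
  if (grepl("[a-z]", records[1L])) {
    stop("a3m master record must contain only uppercase letters")
  }
  flat <- gsub("[a-z.]", "", records)
  lens <- nchar(flat)
  if (any(lens != lens[1L])) {
    bad <- which(lens != lens[1L])[1L]
    stop("a3m record ", bad, " flattens to length ", lens[bad],
         " but master has length ", lens[1L])
  }
  raw_alignment(flat, ids = ids)
}

# ---- integer encoding -------------------------------------------------------

#' Encode a raw alignment as an integer matrix with a depth cap
#'
#' Each residue is mapped to an integer in 1..25 via the
#' \code{\link{residue_vocabulary}}; 0 is reserved for padding.  Only the
#' first \code{min(N, Y)} sequences are kept ("top Y" in aligner output
#' order); if fewer than Y sequences are available, all-zero rows pad the
#' matrix at the bottom so the encoded depth is always exactly Y.
#'
#' @param aln a \code{\link{raw_alignment}}.
#' @param depth_cap Y, the maximum alignment depth (>= 1).
#' @param vocab a \code{\link{residue_vocabulary}}.
#' @return an \code{encoded_msa}: integer matrix of dim Y x L with attributes
#'   \code{L}, \code{N} (original sequence count) and \code{Y}.
#' @export
encode_msa <- function(aln, depth_cap, vocab = residue_vocabulary()) {
  stopifnot(inherits(aln, "raw_alignment"))
  if (depth_cap < 1L) stop("depth_cap must be >= 1")
  Y <- as.integer(depth_cap)
  L <- aln$L
  n_keep <- min(aln$N, Y)
  values <- matrix(0L, nrow = Y, ncol = L)
  for (r in seq_len(n_keep)) {
    values[r, ] <- encode_symbols(strsplit(aln$sequences[r], "")[[1L]], vocab)
  }
  structure(values, L = L, N = aln$N, Y = Y, class = "encoded_msa")
}

#' Decode an encoded MSA back to sequence strings
#'
#' Padding rows (all zero) are dropped.
#'
#' @param msa an \code{encoded_msa}.
#' @param vocab a \code{\link{residue_vocabulary}}.
#' @return character vector of sequences.
#' @export
decode_msa <- function(msa, vocab = residue_vocabulary()) {
  stopifnot(inherits(msa, "encoded_msa"))
  real <- rowSums(unclass(msa) != 0L) > 0L
  apply(unclass(msa)[real, , drop = FALSE], 1L, function(row) {
    paste0(decode_symbols(row, vocab), collapse = "")
  })
}

#' @export
print.encoded_msa <- function(x, ...) {
  cat(sprintf("encoded_msa: depth Y=%d x length L=%d (N=%d sequences)\n",
              attr(x, "Y"), attr(x, "L"), attr(x, "N")))
  invisible(x)
}

# ---- row reordering ---------------------------------------------------------

#' Reorder the aligned sequences under the master
#'
#' The convolutional front end sees blocks of adjacent rows, so the row order
#' of the alignment matters.  Three orderings are supported: \code{native}
#' (aligner output order, the identity), \code{blosum62_sort} (non-master rows
#' sorted by descending total BLOSUM62 similarity to the master, computed over
#' positions where neither sequence has a gap, ties kept in original order)
#' and \code{shuffle} (seeded random permutation of the non-master rows).  The
#' master always stays in row 1, and padding rows of an encoded MSA stay at
#' the bottom.
#'
#' @param x a \code{\link{raw_alignment}} or \code{encoded_msa}.
#' @param mode \code{"native"}, \code{"blosum62_sort"} or \code{"shuffle"}.
#' @param seed integer seed used by \code{shuffle}.
#' @return object of the same class as \code{x}, rows permuted.
#' @export
reorder_sequences <- function(x, mode = c("native", "blosum62_sort", "shuffle"),
                              seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(x, "raw_alignment")) {
    seqs <- x$sequences
    perm <- .row_permutation(seqs, mode, seed)
    raw_alignment(seqs[perm], ids = x$ids[perm])
  } else if (inherits(x, "encoded_msa")) {
    n_real <- sum(rowSums(unclass(x) != 0L) > 0L)
    seqs <- decode_msa(x)
    perm <- .row_permutation(seqs, mode, seed)
    out <- unclass(x)
    out[seq_len(n_real), ] <- out[perm, ]
    attributes(out) <- attributes(x)
    out
  } else {
    stop("x must be a raw_alignment or encoded_msa")
  }
}

# permutation over sequence strings, master fixed at 1
.row_permutation <- function(seqs, mode, seed) {
  n <- length(seqs)
  if (mode == "native") return(seq_len(n))
  rest <- setdiff(seq_len(n), 1L)
  if (length(rest) <= 1L) return(seq_len(n))
  if (mode == "shuffle") {
    old <- .Random.seed_save()
    set.seed(seed)
    rest <- sample(rest)
    .Random.seed_restore(old)
    return(c(1L, rest))
  }
  # blosum62_sort
  scores <- vapply(rest, function(r) {
    blosum62_score(seqs[1L], seqs[r])
  }, numeric(1L))
  c(1L, rest[order(-scores)])  # order() is stable: ties keep original order
}

#' Total BLOSUM62 similarity between two aligned sequences
#'
#' Sums BLOSUM62 substitution scores over positions where neither sequence
#' has a gap.  Symbols missing from the matrix (e.g. U) are scored as X.
#'
#' @param a,b aligned sequence strings of equal length.
#' @return numeric score.
#' @export
blosum62_score <- function(a, b) {
  mat <- .blosum62()
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  if (length(ca) != length(cb)) stop("sequences must have equal length")
  keep <- ca != "-" & cb != "-"
  if (!any(keep)) return(0)
  ca <- ca[keep]; cb <- cb[keep]
  ca[!ca %in% rownames(mat)] <- "X"
  cb[!cb %in% rownames(mat)] <- "X"
  sum(mat[cbind(ca, cb)])
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_cache$mat)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    .blosum62_cache$mat <- env$BLOSUM62
  }
  .blosum62_cache$mat
}

# save/restore global RNG so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# ---- sliding windows --------------------------------------------------------

#' Cut per-residue sliding windows from an encoded MSA
#'
#' One window per master residue: window i spans master columns
#' i-(w-1)/2 .. i+(w-1)/2 with all-zero columns where the window extends past
#' the N- or C-terminus.  The master residue being predicted sits in the
#' central column of row 1.
#'
#' @param msa an \code{encoded_msa}.
#' @param width odd window width (default 31).
#' @return list of L \code{msa_window} objects: integer matrices Y x width
#'   with attribute \code{center} (the master residue index).
#' @export
extract_windows <- function(msa, width = 31L) {
  stopifnot(inherits(msa, "encoded_msa"))
  if (width %% 2L == 0L) stop("window width must be odd")
  L <- attr(msa, "L"); Y <- attr(msa, "Y")
  half <- (width - 1L) %/% 2L
  vals <- unclass(msa)
  # pad left/right with zero columns once, then slice
  padded <- cbind(matrix(0L, Y, half), vals, matrix(0L, Y, half))
  lapply(seq_len(L), function(i) {
    w <- padded[, i:(i + width - 1L), drop = FALSE]
    structure(w, center = i, class = "msa_window")
  })
}

#' Stack windows into a model-input tensor
#'
#' @param windows list of \code{msa_window} objects sharing one shape.
#' @return integer array of dim (n_windows, width, Y).
#' @export
windows_tensor <- function(windows) {
  Y <- nrow(windows[[1L]]); width <- ncol(windows[[1L]])
  arr <- array(0L, dim = c(length(windows), width, Y))
  for (b in seq_along(windows)) {
    arr[b, , ] <- t(unclass(windows[[b]]))
  }
  arr
}

# ---- plain-text tensor i/o --------------------------------------------------

#' Write an encoded MSA as a plain-text matrix
#'
#' First line is a header \code{# L N Y}; the remaining Y lines carry the
#' integer rows, space separated.
#'
#' @param msa an \code{encoded_msa}.
#' @param path output path.
#' @export
write_encoded_msa <- function(msa, path) {
  stopifnot(inherits(msa, "encoded_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d %d %d", attr(msa, "L"), attr(msa, "N"),
                     attr(msa, "Y")), con)
  utils::write.table(unclass(msa), con, row.names = FALSE,
                     col.names = FALSE, sep = " ")
}

#' Read an encoded MSA written by \code{\link{write_encoded_msa}}
#'
#' @param path input path.
#' @return an \code{encoded_msa}.
#' @export
read_encoded_msa <- function(path) {
  hdr <- scan(path, what = character(), nlines = 1L, quiet = TRUE)
  meta <- as.integer(hdr[-1L])
  vals <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(vals) <- NULL
  storage.mode(vals) <- "integer"
  structure(vals, L = meta[1L], N = meta[2L], Y = meta[3L],
            class = "encoded_msa")
}
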