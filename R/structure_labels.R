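# Ground-truth label generation: secondary structure, relative solvent
# accessibility and contact maps, from DSSP output and PDB coordinates.

#' Parse a DSSP output file
#'
#' Reads the per-residue data section of a classic DSSP output file (fixed
#' columns).  Chain-break rows (residue code \code{!}) are skipped; a blank
#' structure column is reported as C (coil); lowercase residue codes (DSSP's
#' convention for disulfide-bonded cysteines) become C(ys).
#'
#' @param path path to a DSSP file.
#' @return data.frame with columns \code{chain}, \code{resnum},
#'   \code{residue} (one-letter code), \code{ss8} and \code{asa} (absolute
#'   accessible surface, square Angstrom).
#' @export
parse_dssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) == 0L) {
    stop("not a DSSP file: data section header ('  #  RESIDUE ...') missing")
  }
  body <- lines[(start[1L] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  recs <- lapply(body, function(ln) {
    aa <- substr(ln, 14L, 14L)
    if (aa == "!") return(NULL)                    # chain break
    if (aa %in% letters) aa <- "C"                 # SS-bonded cysteine
    resnum <- suppressWarnings(as.integer(trimws(substr(ln, 6L, 10L))))
    asa <- suppressWarnings(as.numeric(trimws(substr(ln, 35L, 38L))))
    if (is.na(resnum) || is.na(asa)) stop("unparseable DSSP row: ", ln)
    ss8 <- substr(ln, 17L, 17L)
    if (ss8 == " ") ss8 <- "C"
    data.frame(chain = substr(ln, 12L, 12L), resnum = resnum,
               residue = aa, ss8 = ss8, asa = asa,
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1L))]
  if (length(recs) == 0L) stop("DSSP file contains no residue records")
  do.call(rbind, recs)
}

#' Reduce 8-class DSSP secondary structure to 3 classes
#'
#' The standard reduction: helices \{H, G, I\} -> H, extended/bridge
#' \{E, B\} -> E, everything else \{S, T, C, blank\} -> C.
#'
#' @param ss8 character vector of 8-class symbols.
#' @return character vector over \{H, E, C\}.
#' @export
reduce_ss8_to_ss3 <- function(ss8) {
  ss8[ss8 == " " | ss8 == ""] <- "C"
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           S = "C", T = "C", C = "C")
  out <- map[ss8]
  if (anyNA(out)) {
    stop("unknown secondary-structure symbol: ",
         paste(unique(ss8[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Relative solvent accessibility from absolute ASA
#'
#' RSA = ASA / MaxASA(residue), clipped at 1 (DSSP occasionally reports areas
#' above the theoretical maximum).
#'
#' @param asa absolute accessible surface area(s), square Angstrom.
#' @param residue one-letter residue code(s).
#' @param table MaxASA lookup, default \code{\link{max_asa_table}}.
#' @return numeric fraction(s) in [0, 1].
#' @export
compute_rsa <- function(asa, residue, table = max_asa_table()) {
  if (any(asa < 0)) stop("asa must be non-negative")
  mx <- table[residue]
  if (anyNA(mx)) {
    stop("residue(s) absent from MaxASA table: ",
         paste(unique(residue[is.na(mx)]), collapse = ", "))
  }
  pmin(asa / unname(mx), 1)
}

#' Classify RSA fractions into accessibility classes
#'
#' Four-class thresholds: [0, 0.04] Buried, (0.04, 0.25] PartiallyBuried,
#' (0.25, 0.5] PartiallyAccessible, (0.5, 1] Accessible.  Two-class:
#' [0, 0.25] Buried, (0.25, 1] Accessible.  Boundaries are right-closed as
#' written.
#'
#' @param rsa numeric fraction(s) in [0, 1].
#' @param scheme \code{"four"} or \code{"two"}.
#' @return character class labels.
#' @export
classify_rsa <- function(rsa, scheme = c("four", "two")) {
  scheme <- match.arg(scheme)
  if (any(rsa < 0 | rsa > 1)) stop("rsa must lie in [0, 1]")
  if (scheme == "four") {
    breaks <- c(-Inf, 0.04, 0.25, 0.5, Inf)
    labels <- c("Buried", "PartiallyBuried", "PartiallyAccessible",
                "Accessible")
  } else {
    breaks <- c(-Inf, 0.25, Inf)
    labels <- c("Buried", "Accessible")
  }
  as.character(cut(rsa, breaks = breaks, labels = labels, right = TRUE))
}

#' Build per-residue structure labels from parsed DSSP records
#'
#' @param dssp data.frame as returned by \code{\link{parse_dssp}} (one chain).
#' @param table MaxASA lookup table.
#' @return a \code{structure_labels} list: \code{ss3}, \code{rsa},
#'   \code{rsa4}, \code{rsa2}, \code{residue}, all of length L.
#' @export
structure_labels <- function(dssp, table = max_asa_table()) {
  known <- dssp$residue %in% names(table)
  rsa <- rep(NA_real_, nrow(dssp))
  rsa[known] <- compute_rsa(dssp$asa[known], dssp$residue[known], table)
  rsa4 <- rsa2 <- rep(NA_character_, nrow(dssp))
  rsa4[known] <- classify_rsa(rsa[known], "four")
  rsa2[known] <- classify_rsa(rsa[known], "two")
  structure(
    list(ss3 = reduce_ss8_to_ss3(dssp$ss8), rsa = rsa,
         rsa4 = rsa4, rsa2 = rsa2, residue = dssp$residue),
    class = "structure_labels"
  )
}

#' Write structure labels as a tab-separated table
#'
#' @param labels a \code{structure_labels} object.
#' @param path output path.
#' @export
write_labels <- function(labels, path) {
  df <- data.frame(position = seq_along(labels$ss3),
                   residue = labels$residue, ss3 = labels$ss3,
                   rsa = labels$rsa, rsa4 = labels$rsa4, rsa2 = labels$rsa2)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# ---- contact maps -----------------------------------------------------------

#' Binary contact map from representative-atom coordinates
#'
#' Two residues are in contact when the Euclidean distance between their
#' representative atoms (C-beta; C-alpha for glycine) is strictly below the
#' cutoff.  Residues with missing coordinates (NA rows) are masked: their
#' rows/columns are NA and are excluded from evaluation.
#'
#' @param coords numeric matrix L x 3 of representative-atom positions; NA
#'   rows mark residues with missing density.
#' @param cutoff contact distance cutoff in Angstrom (default 8).
#' @return a \code{contact_map}: integer L x L matrix (1 contact, 0 not,
#'   NA masked) with attribute \code{mask} (logical, TRUE = missing).
#' @export
contact_map_from_coords <- function(coords, cutoff = 8) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an L x 3 matrix")
  mask <- !stats::complete.cases(coords)
  if (all(mask)) stop("no residue has coordinates")
  d <- as.matrix(stats::dist(coords))
  cm <- matrix(NA_integer_, nrow(coords), nrow(coords))
  ok <- !mask
  cm[ok, ok] <- as.integer(d[ok, ok] < cutoff)
  structure(cm, mask = mask, class = "contact_map")
}

#' Extract representative-atom coordinates from a PDB file
#'
#' Uses the C-beta atom of each residue (C-alpha for glycine); residues
#' lacking the representative atom get an NA row.  Alternate locations keep
#' the highest-occupancy record (first on ties).
#'
#' @param path path to a PDB-format file.
#' @param chain optional chain identifier; default: first chain in the file.
#' @return numeric matrix L x 3, rownames = residue numbers.
#' @export
pdb_representative_coords <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain == chain, , drop = FALSE]
  resnos <- unique(at$resno)
  coords <- matrix(NA_real_, length(resnos), 3L,
                   dimnames = list(resnos, c("x", "y", "z")))
  for (k in seq_along(resnos)) {
    res <- at[at$resno == resnos[k], , drop = FALSE]
    want <- if (res$resid[1L] == "GLY") "CA" else "CB"
    hit <- res[res$elety == want, , drop = FALSE]
    if (nrow(hit) == 0L) next
    if (nrow(hit) > 1L) {            # altLoc: highest occupancy, first on tie
      hit <- hit[order(-hit$o), , drop = FALSE]
    }
    coords[k, ] <- as.numeric(hit[1L, c("x", "y", "z")])
  }
  coords
}

#' Long-range residue pairs
#'
#' All unordered pairs (i, j), i < j, with sequence separation |i - j|
#' strictly greater than \code{min_sep_over} (default 23, i.e. separation
#' >= 24, the CASP long-range definition).
#'
#' @param L protein length.
#' @param min_sep_over pairs must satisfy |i - j| > this value.
#' @return two-column integer matrix (i, j); zero rows when none qualify.
#' @export
long_range_pairs <- function(L, min_sep_over = 23L) {
  if (L < 1L) stop("L must be >= 1")
  if (L <= min_sep_over + 1L) {
    return(matrix(integer(0L), ncol = 2L,
                  dimnames = list(NULL, c("i", "j"))))
  }
  idx <- which(outer(seq_len(L), seq_len(L),
                     function(i, j) j - i > min_sep_over), arr.ind = TRUE)
  out <- cbind(i = idx[, 1L], j = idx[, 2L])
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}
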