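# Fixture builders shared across the test files.  Everything is generated
# in code at test time; nothing binary is read from disk.

write_tmp_fasta <- function(seqs, ids = paste0("s", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# minimal but structurally faithful DSSP output: header, column ruler,
# then fixed-column residue rows
write_tmp_dssp <- function(residues, ss8, acc, chain = "A",
                           breaks = integer(0)) {
  path <- tempfile(fileext = ".dssp")
  lines <- c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  )
  n <- 0L
  for (k in seq_along(residues)) {
    if (k %in% breaks) {
      lines <- c(lines, paste0(sprintf("%5d", n + 1L), strrep(" ", 8L), "!"))
      n <- n + 1L
    }
    # fixed columns: resnum 6-10, chain 12, AA 14, SS 17, ACC 35-38
    row <- sprintf("%5d%5d %s %s  %s%s%4d", n + 1L, k, chain,
                   residues[k], ss8[k], strrep(" ", 17L), acc[k])
    lines <- c(lines, row)
    n <- n + 1L
  }
  writeLines(lines, path)
  path
}

# toy PDB with CA for every residue and CB for non-glycine residues
write_tmp_pdb <- function(coords, resids, chain = "A") {
  path <- tempfile(fileext = ".pdb")
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(coords))) {
    for (atom in c("CA", "CB")) {
      if (atom == "CB" && resids[i] == "GLY") next
      serial <- serial + 1L
      # CB sits exactly at the representative coordinate; CA is offset for
      # non-Gly so a CA/CB mixup would be caught
      xyz <- coords[i, ]
      if (atom == "CA" && resids[i] != "GLY") xyz <- xyz + 1.5
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, atom, resids[i], chain, i, xyz[1], xyz[2], xyz[3],
        substr(atom, 1, 1)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

random_simplex <- function(k) {
  x <- stats::runif(k)
  x / sum(x)
}

# exhaustive reference for the top-L/5 long-range precision metric
oracle_top_l5 <- function(pred, truth, min_sep_over = 23L) {
  L <- nrow(pred)
  rows <- data.frame(i = integer(), j = integer(), p = numeric(),
                     t = integer())
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j > i && j - i > min_sep_over && !is.na(truth[i, j])) {
      rows <- rbind(rows, data.frame(i = i, j = j, p = pred[i, j],
                                     t = truth[i, j]))
    }
  }
  rows <- rows[order(-rows$p, rows$i, rows$j), ]
  n_sel <- min(max(1L, L %/% 5L), nrow(rows))
  sum(rows$t[seq_len(n_sel)]) / n_sel
}
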