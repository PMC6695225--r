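test_that("flat FASTA alignments parse with the first record as master", {
  path <- write_tmp_fasta(c("ACDEFGHI", "ac-efghi", "ACDEF-HI"))
  aln <- read_alignment(path, "fasta")
  expect_s3_class(aln, "raw_alignment")
  expect_equal(aln$N, 3L)
  expect_equal(aln$L, 8L)
  expect_equal(aln$sequences[1L], "ACDEFGHI")  # case-insensitive
})

test_that("ragged, empty and illegal alignments are rejected", {
  expect_error(read_alignment(write_tmp_fasta(c("ACDEFGHI", "ACDEFGH"))),
               "ragged")
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_alignment(empty), "no sequences")
  expect_error(raw_alignment(c("AC3D", "ACDD")), "illegal")
})

test_that("a3m flattening removes insertions and enforces master length", {
  aln <- flatten_a3m(c("ACD", "A-Dg"))
  expect_equal(aln$sequences, c("ACD", "A-D"))
  # no lowercase: identity
  expect_equal(flatten_a3m(c("ACD", "AC-"))$sequences, c("ACD", "AC-"))
  # a hit that flattens to the wrong length fails
  expect_error(flatten_a3m(c("ACD", "Agg")), "flattens to length")
  expect_error(flatten_a3m(c("aCD", "ACD")), "uppercase")
})

test_that("columns where the master is gapped are removed", {
  aln <- raw_alignment(c("A-CD", "AWCE"))
  expect_equal(aln$L, 3L)
  expect_equal(aln$sequences, c("ACD", "ACE"))
})

test_that("encoding follows the stated 1..25 mapping with a depth cap", {
  aln <- raw_alignment(c("ACD", "A-D"))
  e <- encode_msa(aln, depth_cap = 2)
  expect_equal(unclass(e), matrix(c(1L, 1L, 2L, 25L, 3L, 3L), 2, 3),
               ignore_attr = TRUE)
  # zero rows pad the bottom when N < Y
  e4 <- encode_msa(aln, depth_cap = 4)
  expect_equal(dim(unclass(e4)), c(4L, 3L))
  expect_true(all(unclass(e4)[3:4, ] == 0L))
  # real rows never contain the padding value
  expect_true(all(unclass(e4)[1:2, ] > 0L))
  expect_error(encode_msa(aln, depth_cap = 0), ">= 1")
})

test_that("letters outside the 25-symbol vocabulary collapse to X", {
  aln <- raw_alignment(c("AJD"))
  expect_equal(unclass(encode_msa(aln, 1))[1, ], c(1L, 24L, 3L))
  expect_equal(encode_symbols(c("O", "J", "X")), c(24L, 24L, 24L))
})

test_that("encoding is a bijection on the 25 symbols and round-trips", {
  v <- residue_vocabulary()
  idx <- encode_symbols(v$index_to_symbol)
  expect_equal(sort(idx), 1:25)
  expect_equal(decode_symbols(idx), v$index_to_symbol)
  # full MSA round trip
  set.seed(5)
  seqs <- replicate(4, paste0(sample(v$index_to_symbol[1:24], 12, TRUE),
                              collapse = ""))
  aln <- raw_alignment(seqs)
  expect_equal(decode_msa(encode_msa(aln, 10)), aln$sequences)
})

test_that("reorder_sequences keeps the master first in every mode", {
  aln <- raw_alignment(c("AAA", "YYY", "AAA"))
  expect_equal(reorder_sequences(aln, "native")$sequences, aln$sequences)
  # BLOSUM62: AAA scores 3*4 = 12 against master, YYY scores 3*(-2) = -6
  srt <- reorder_sequences(aln, "blosum62_sort")
  expect_equal(srt$sequences, c("AAA", "AAA", "YYY"))
  expect_equal(blosum62_score("AAA", "AAA"), 12)
  expect_equal(blosum62_score("AAA", "YYY"), -6)
  # gap positions are skipped, not penalised
  expect_equal(blosum62_score("AAA", "A-A"), 8)
})

test_that("shuffle reordering is a seeded permutation of non-master rows", {
  set.seed(99)
  seqs <- c("MASTERSEQ", replicate(8, paste0(sample(LETTERS[c(1, 3:9)], 9,
                                                    TRUE), collapse = "")))
  seqs <- gsub("B", "A", seqs)
  aln <- raw_alignment(seqs)
  s1 <- reorder_sequences(aln, "shuffle", seed = 7)
  s2 <- reorder_sequences(aln, "shuffle", seed = 7)
  expect_identical(s1$sequences, s2$sequences)
  expect_equal(s1$sequences[1L], aln$sequences[1L])
  expect_setequal(s1$sequences[-1L], aln$sequences[-1L])
  # every mode preserves the multiset of rows
  for (mode in c("native", "blosum62_sort", "shuffle")) {
    out <- reorder_sequences(aln, mode, seed = 3)
    expect_equal(sort(out$sequences), sort(aln$sequences))
  }
  expect_error(reorder_sequences(aln, "upside_down"), "arg")
})

test_that("window extraction yields L centered, zero-padded windows", {
  aln <- raw_alignment(c("ACD"))
  e <- encode_msa(aln, 2)
  w <- extract_windows(e, 31)
  expect_length(w, 3L)
  # window for residue 1: 15 leading all-zero columns
  expect_true(all(unclass(w[[1L]])[, 1:15] == 0L))
  expect_equal(unclass(w[[1L]])[1L, 16L], 1L)
  expect_error(extract_windows(e, 30), "odd")
})

test_that("window centers tile the master row on random alignments", {
  set.seed(11)
  v <- residue_vocabulary()
  for (rep in 1:10) {
    L <- sample(5:40, 1)
    N <- sample(1:6, 1)
    seqs <- replicate(N, paste0(sample(v$index_to_symbol[1:20], L, TRUE),
                                collapse = ""))
    e <- encode_msa(raw_alignment(seqs), depth_cap = 4)
    w <- extract_windows(e, 31)
    expect_length(w, L)
    centers <- vapply(seq_len(L), function(i) unclass(w[[i]])[1L, 16L],
                      integer(1L))
    expect_equal(centers, unclass(e)[1L, ])
    for (i in c(1L, L)) {
      expect_equal(attr(w[[i]], "center"), i)
    }
  }
})

test_that("encoded MSAs round-trip through the plain-text format", {
  e <- encode_msa(raw_alignment(c("ACDEF", "AC-EF")), 4)
  path <- tempfile(fileext = ".txt")
  write_encoded_msa(e, path)
  e2 <- read_encoded_msa(path)
  expect_equal(unclass(e2), unclass(e), ignore_attr = TRUE)
  expect_equal(attr(e2, "L"), attr(e, "L"))
  expect_equal(attr(e2, "Y"), attr(e, "Y"))
})
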