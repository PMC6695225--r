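test_that("embedding lookup maps equal indices to equal vectors", {
  x <- matrix(c(3L, 7L, 3L, 0L), 2, 2)
  out <- apply_embedding(x, E = 4, seed = 2)
  expect_equal(dim(out), c(2L, 2L, 4L))
  expect_equal(out[1, 1, ], out[1, 2, ])  # both index 3
  expect_false(isTRUE(all.equal(out[1, 1, ], out[2, 1, ])))
  expect_error(apply_embedding(matrix(26L), E = 4), "outside vocabulary")
})

test_that("the embedded window has the documented 31 x 500 x 10 shape", {
  x <- matrix(sample(0:25, 31 * 500, TRUE), 31, 500)
  out <- apply_embedding(x, E = 10, seed = 1)
  expect_equal(dim(out), c(31L, 500L, 10L))
})

test_that("one conv/pool stage reduces depth 500 to 50 with a 1x10 window", {
  set.seed(3)
  x <- array(rnorm(31 * 500 * 10), c(31, 500, 10))
  out <- column_conv_pool_stage(x, window = 10, filters = 10, seed = 4)
  expect_equal(dim(out), c(31L, 50L, 10L))
  # floor rule for non-divisible depths
  x2 <- array(rnorm(31 * 55 * 10), c(31, 55, 10))
  expect_equal(dim(column_conv_pool_stage(x2, 10, 10, seed = 4))[2L], 5L)
  expect_error(column_conv_pool_stage(array(0, c(5, 4, 2)), 10, 3),
               "smaller than")
})

test_that("column stages never mix information across columns", {
  set.seed(6)
  x <- array(rnorm(9 * 12 * 3), c(9, 12, 3))
  out1 <- column_conv_pool_stage(x, window = 3, filters = 4, seed = 10)
  x2 <- x
  x2[5, , ] <- rnorm(12 * 3)
  out2 <- column_conv_pool_stage(x2, window = 3, filters = 4, seed = 10)
  changed <- which(apply(abs(out1 - out2), 1, max) > 1e-12)
  expect_equal(changed, 5L)
})

test_that("outer_product_expand matches the brute-force definition", {
  H <- array(c(2, 3), c(2, 1, 1))
  expect_equal(outer_product_expand(H)[, , 1],
               matrix(c(4, 6, 6, 9), 2, 2))
  H2 <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  expect_equal(dim(outer_product_expand(H2)), c(5L, 5L, 12L))
})

test_that("per-residue model outputs simplex vectors deterministically", {
  hp <- ss_rsa_hyperparams(E = 4, Y = 8, window = 7, pool_window = 4,
                           lstm_units = 5, fc_units = c(8, 8), dropout = 0.4,
                           n_classes = 3, class_labels = c("H", "E", "C"))
  m <- build_ss_rsa_model(hp, seed = 3)
  set.seed(1)
  seqs <- replicate(5, paste0(sample(c("A", "E", "V", "G"), 12, TRUE),
                              collapse = ""))
  enc <- encode_msa(raw_alignment(seqs), 8)
  p1 <- predict_ss_rsa(m, enc)
  p2 <- predict_ss_rsa(m, enc)
  expect_identical(p1, p2)  # inference is deterministic despite dropout > 0
  expect_equal(dim(p1), c(12L, 3L))
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), rep(1, 12), tolerance = 1e-9)
  expect_equal(colnames(p1), c("H", "E", "C"))
})

test_that("invalid hyperparameters are rejected at construction", {
  expect_error(ss_rsa_hyperparams(E = 0), "E must be")
  expect_error(ss_rsa_hyperparams(n_classes = 5), "n_classes")
  expect_error(ss_rsa_hyperparams(dropout = 1), "dropout")
  expect_error(cmap_hyperparams(cmap_trunk_depth = 0), "cmap_trunk_depth")
  expect_error(cmap_hyperparams(E = 4, Y = 3, pool_window = 4), "exhausted")
})

test_that("one CMAP model handles different protein lengths without rebuild", {
  hp <- cmap_hyperparams(E = 4, Y = 6, pool_window = 3, n_column_stages = 1,
                         cmap_trunk_depth = 2, cmap_filters = 6)
  m <- build_cmap_model(hp, seed = 9)
  set.seed(2)
  for (L in c(40L, 64L)) {
    seqs <- replicate(6, paste0(sample(c("K", "E", "A", "G"), L, TRUE),
                                collapse = ""))
    enc <- encode_msa(raw_alignment(seqs), 6)
    P <- predict_contacts(m, enc)
    expect_equal(dim(P), c(L, L))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("the CMAP softmax head emits per-pair distributions", {
  hp <- cmap_hyperparams(E = 3, Y = 4, pool_window = 2, n_column_stages = 1,
                         cmap_trunk_depth = 2, cmap_filters = 4)
  m <- build_cmap_model(hp, seed = 1)
  idx <- matrix(sample(1:25, 30 * 4, TRUE), 30, 4)
  fw <- rawmsa:::.cmap_forward(m, idx, train = FALSE)
  probs <- rawmsa:::.softmax(fw$logits)
  expect_equal(dim(probs), c(900L, 2L))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 900), tolerance = 1e-9)
})

test_that("embedding similarity ranks neighbours by cosine", {
  emb <- matrix(0, 25, 4)
  emb[1, ] <- c(1, 0, 0, 0)    # A (query)
  emb[2, ] <- c(2, 0, 0, 0)    # C: parallel, cosine 1
  emb[3, ] <- c(0, 1, 0, 0)    # D: orthogonal, cosine 0
  emb[4, ] <- c(-1, 0, 0, 0)   # E: antiparallel, cosine -1
  nb <- embedding_similarity(emb, "A", k = 3)
  expect_equal(nb$symbol[1L], "C")
  expect_equal(nb$cosine[1L], 1.0)
  expect_equal(nb$cosine[2L], 0.0)
  all24 <- embedding_similarity(emb, "A", k = 24)
  expect_equal(nrow(all24), 24L)
  expect_false("A" %in% all24$symbol)
  expect_true(all(diff(all24$cosine) <= 1e-12))
  expect_error(embedding_similarity(emb, "A", k = 25), "k must be")
  expect_error(embedding_similarity(emb, "?", k = 3), "unknown residue")
})

test_that("hyperparameters round-trip through the JSON config format", {
  hp <- cmap_hyperparams(E = 12, Y = 64, pool_window = 8,
                         cmap_trunk_depth = 8)
  path <- tempfile(fileext = ".json")
  write_hyperparams(hp, path)
  hp2 <- read_hyperparams(path)
  expect_equal(hp2$E, 12L)
  expect_equal(hp2$cmap_trunk_depth, 8L)
  expect_equal(hp2$task, "cmap")
})
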