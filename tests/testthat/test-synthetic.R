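mutual_information <- function(a, b) {
  tb <- table(a, b)
  p <- tb / sum(tb)
  sum(p * log(p / outer(rowSums(p), colSums(p))), na.rm = TRUE)
}

test_that("generators are pure functions of (cfg, seed)", {
  cfg <- synthetic_config(L = 40, N = 30, seed = 9)
  g1 <- generate_ss_msa(cfg, seed = 9)
  g2 <- generate_ss_msa(cfg, seed = 9)
  expect_identical(g1$alignment$sequences, g2$alignment$sequences)
  expect_identical(g1$labels, g2$labels)
  c1 <- generate_contact_msa(cfg, seed = 9)
  c2 <- generate_contact_msa(cfg, seed = 9)
  expect_identical(c1$alignment$sequences, c2$alignment$sequences)
  expect_identical(unclass(c1$map), unclass(c2$map))
  expect_false(identical(generate_ss_msa(cfg, seed = 10)$labels, g1$labels))
})

test_that("in the noiseless limit the column residue set identifies the class", {
  cfg <- synthetic_config(L = 50, N = 40, emission_strength = 1,
                          gap_rate = 0, seed = 3)
  g <- generate_ss_msa(cfg)
  M <- do.call(rbind, strsplit(g$alignment$sequences, ""))
  sets <- list(H = c("A", "E", "L", "M"), E = c("V", "I", "Y", "W"),
               C = c("G", "P", "N", "S"))
  inferred <- apply(M, 2L, function(col) {
    names(sets)[vapply(sets, function(s) all(col %in% s), logical(1L))]
  })
  expect_equal(inferred, g$labels)
})

test_that("label frequencies match the chain's stationary distribution", {
  cfg <- synthetic_config(seed = 1)   # defaults: L = 60, stay 0.9
  labs <- unlist(lapply(generate_ss_dataset(cfg, n = 50), `[[`, "labels"))
  # the symmetric sticky chain has uniform stationary distribution 1/3
  freqs <- table(labs) / length(labs)
  expect_true(all(abs(freqs - 1 / 3) < 0.05))
})

test_that("labels cover the alignment width for every task", {
  cfg <- synthetic_config(L = 30, N = 10, seed = 2)
  for (task in c("ss", "rsa4", "rsa2")) {
    g <- generate_ss_msa(cfg, task = task)
    expect_length(g$labels, 30L)
    expect_equal(g$alignment$L, 30L)
    expect_true(all(g$labels %in% g$levels))
  }
})

test_that("planted pairs carry covariation; uncoupled columns do not", {
  cfg <- synthetic_config(L = 60, N = 500, seed = 5)
  g <- generate_contact_msa(cfg)
  M <- do.call(rbind, strsplit(g$alignment$sequences, ""))
  lr <- long_range_pairs(60)
  mis <- apply(lr, 1L, function(pr) mutual_information(M[, pr[1L]],
                                                       M[, pr[2L]]))
  planted <- unclass(g$map)[lr] == 1L
  expect_gt(min(mis[planted]), quantile(mis[!planted], 0.99))
  # independence limit: no coupling, no excess mutual information
  cfg0 <- synthetic_config(L = 60, N = 500, coupling_strength = 0, seed = 5)
  g0 <- generate_contact_msa(cfg0)
  M0 <- do.call(rbind, strsplit(g0$alignment$sequences, ""))
  p0 <- g0$pairs
  mis0 <- apply(p0, 1L, function(pr) mutual_information(M0[, pr[1L]],
                                                        M0[, pr[2L]]))
  # ML MI estimates on 20x20 tables from N=500 have positive bias ~ 0.4;
  # what matters is that "planted" pairs look like background pairs
  bg <- apply(lr[sample(nrow(lr), 20L), ], 1L,
              function(pr) mutual_information(M0[, pr[1L]], M0[, pr[2L]]))
  expect_lt(abs(mean(mis0) - mean(bg)), 0.1)
})

test_that("the planted map is symmetric with no off-plant long-range contact", {
  cfg <- synthetic_config(L = 40, N = 30, seed = 6)
  g <- generate_contact_msa(cfg)
  cm <- unclass(g$map)
  expect_identical(cm, t(cm))
  lr <- long_range_pairs(40)
  on_plant <- paste(g$pairs[, 1L], g$pairs[, 2L])
  all_lr <- paste(lr[, 1L], lr[, 2L])
  expect_equal(sum(cm[lr]), nrow(g$pairs))
  expect_true(all(cm[lr[!(all_lr %in% on_plant), , drop = FALSE]] == 0L))
  # endpoint-disjoint planting
  expect_equal(anyDuplicated(as.vector(g$pairs)), 0L)
  expect_error(generate_contact_msa(synthetic_config(L = 20, seed = 1)),
               ">= 25")
})

test_that("the toy chain has contacts exactly at separations <= 2", {
  toy <- generate_toy_structure(12, seed = 3)
  sep <- abs(outer(1:12, 1:12, `-`))
  expect_equal(unclass(toy$map), matrix(as.integer(sep <= 2), 12, 12),
               ignore_attr = TRUE)
  # the realised coordinates reproduce the analytic map
  cm <- contact_map_from_coords(toy$coords)
  expect_equal(unclass(cm), unclass(toy$map), ignore_attr = TRUE)
  # L = 2: the single 3.8 A pair is a contact
  toy2 <- generate_toy_structure(2, seed = 1)
  expect_equal(unclass(toy2$map)[1L, 2L], 1L)
  # different rigid motions, identical map
  expect_equal(unclass(generate_toy_structure(12, seed = 8)$map),
               unclass(toy$map), ignore_attr = TRUE)
  expect_error(generate_toy_structure(1), ">= 2")
})

test_that("generated FASTA survives a write/read round trip", {
  cfg <- synthetic_config(L = 30, N = 8, seed = 4)
  g <- generate_ss_msa(cfg)
  path <- tempfile(fileext = ".fasta")
  write_fasta(g$alignment, path)
  back <- read_alignment(path, "fasta")
  expect_identical(back$sequences, g$alignment$sequences)
})
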