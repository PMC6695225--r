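# Desk-scale synthetic data with the statistical structure the networks must
# learn: columns whose residue composition depends on a hidden per-column
# class (secondary structure / accessibility learnability), and planted
# inter-column covariation at long-range pairs (contact learnability).

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# class-specific residue subsets, loosely following helix/sheet/coil
# propensities (helix formers, beta-branched/aromatic, turn breakers) and
# hydrophobicity for the accessibility states
.EMISSION_SETS <- list(
  ss = list(H = c("A", "E", "L", "M"), E = c("V", "I", "Y", "W"),
            C = c("G", "P", "N", "S")),
  rsa4 = list(Buried = c("F", "I", "L", "V"),
              PartiallyBuried = c("A", "C", "M", "W"),
              PartiallyAccessible = c("G", "H", "S", "T"),
              Accessible = c("D", "E", "K", "R")),
  rsa2 = list(Buried = c("F", "I", "L", "V", "A", "C", "M", "W"),
              Accessible = c("D", "E", "K", "R", "G", "H", "S", "T"))
)

# complementary residue pairs emitted jointly at planted contact pairs
# (salt-bridge-like charge pairing)
.COUPLING_PATTERNS <- list(first = c("K", "R", "E", "D"),
                           second = c("E", "D", "K", "R"))

#' Configuration for the synthetic-data generators
#'
#' @param L master sequence length.
#' @param N sequences per alignment (including the master).
#' @param n_proteins number of proteins in a generated dataset.
#' @param stay_prob probability that the hidden per-column class chain stays
#'   in its current state (off-diagonal mass is spread evenly).
#' @param emission_strength probability that a cell emits from its column
#'   class's residue subset rather than uniformly from all 20 residues.
#' @param gap_rate per-cell gap probability in non-master rows.
#' @param contact_density fraction of long-range pairs planted as contacts.
#' @param coupling_strength probability that a sequence emits a
#'   complementary residue pair at a planted contact pair.
#' @param seed base RNG seed.
#' @return list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(L = 60L, N = 200L, n_proteins = 50L,
                             stay_prob = 0.9, emission_strength = 0.7,
                             gap_rate = 0.05, contact_density = 0.05,
                             coupling_strength = 0.8, seed = 1L) {
  probs <- c(stay_prob, emission_strength, gap_rate, contact_density,
             coupling_strength)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (L < 1L || N < 1L || n_proteins < 1L) {
    stop("L, N and n_proteins must be positive")
  }
  structure(list(L = as.integer(L), N = as.integer(N),
                 n_proteins = as.integer(n_proteins), stay_prob = stay_prob,
                 emission_strength = emission_strength, gap_rate = gap_rate,
                 contact_density = contact_density,
                 coupling_strength = coupling_strength,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# k-state symmetric sticky transition matrix
.transition_matrix <- function(k, stay) {
  m <- matrix((1 - stay) / (k - 1), k, k)
  diag(m) <- stay
  m
}

# hidden class path of length L over `states` from the sticky chain
.markov_path <- function(L, states, stay) {
  k <- length(states)
  path <- integer(L)
  path[1L] <- sample.int(k, 1L)
  if (L > 1L) {
    for (i in 2L:L) {
      path[i] <- if (stats::runif(1L) < stay) path[i - 1L]
                 else sample(setdiff(seq_len(k), path[i - 1L]), 1L)
    }
  }
  states[path]
}

#' Generate an MSA with class-dependent column composition
#'
#' A hidden per-column class path is drawn from a sticky Markov chain; every
#' sequence then emits, per column, a residue from the class-specific subset
#' with probability \code{emission_strength} (uniform over the 20 standard
#' residues otherwise).  Gaps are injected into non-master rows at
#' \code{gap_rate}; the master is emitted by the same residue process but
#' receives no gaps, since master-gap columns would not be master-indexable.
#' The labels are the hidden path.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param task \code{"ss"} (3 classes H/E/C), \code{"rsa4"} or \code{"rsa2"}.
#' @param seed RNG seed (defaults to \code{cfg$seed}); the generator is a
#'   pure function of (cfg, seed).
#' @return list with \code{alignment} (a \code{\link{raw_alignment}}),
#'   \code{labels} (character vector of length L), \code{levels} (class
#'   labels in model order) and \code{task}.
#' @export
generate_ss_msa <- function(cfg, task = c("ss", "rsa4", "rsa2"),
                            seed = cfg$seed) {
  task <- match.arg(task)
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  set.seed(seed)
  sets <- .EMISSION_SETS[[task]]
  states <- names(sets)
  path <- .markov_path(cfg$L, states, cfg$stay_prob)
  M <- matrix(sample(.AA20, cfg$N * cfg$L, replace = TRUE), cfg$N, cfg$L)
  for (j in seq_len(cfg$L)) {
    set_j <- sets[[path[j]]]
    use_class <- stats::runif(cfg$N) < cfg$emission_strength
    M[use_class, j] <- sample(set_j, sum(use_class), replace = TRUE)
  }
  if (cfg$N > 1L && cfg$gap_rate > 0) {
    sub <- M[-1L, , drop = FALSE]
    sub[stats::runif(length(sub)) < cfg$gap_rate] <- "-"
    M[-1L, ] <- sub
  }
  .Random.seed_restore(old)
  aln <- raw_alignment(apply(M, 1L, paste0, collapse = ""))
  list(alignment = aln, labels = path, levels = states, task = task)
}

#' Generate an MSA with planted long-range covariation and its contact map
#'
#' Planted contact pairs are drawn uniformly from the long-range pairs
#' (|i - j| > 23) at \code{contact_density}.  For each sequence and planted
#' pair, with probability \code{coupling_strength} the two positions jointly
#' emit a complementary charge pair ((K,E), (R,D), (E,K) or (D,R)); all
#' other cells are independent uniform over the 20 standard residues.
#' Planted pairs are endpoint-disjoint (each column belongs to at most one
#' pair), so every planted pair keeps its full coupling signal and no
#' spurious covariation leaks between non-planted pairs through shared
#' partners; the planted count is therefore capped at floor(L/2).  The truth
#' map contains exactly the planted pairs (plus the trivial self-contact
#' diagonal).
#'
#' @param cfg a \code{\link{synthetic_config}} with \code{L >= 25}.
#' @param seed RNG seed (defaults to \code{cfg$seed}).
#' @return list with \code{alignment}, \code{map} (a \code{contact_map}) and
#'   \code{pairs} (the planted pair index matrix).
#' @export
generate_contact_msa <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$L < 25L) stop("L must be >= 25 so that long-range pairs exist")
  old <- .Random.seed_save()
  set.seed(seed)
  lr <- long_range_pairs(cfg$L)
  n_plant <- min(max(1L, round(cfg$contact_density * nrow(lr))),
                 cfg$L %/% 2L)
  # draw pairs one at a time, discarding candidates that reuse an endpoint
  cand <- lr[sample.int(nrow(lr)), , drop = FALSE]
  used <- rep(FALSE, cfg$L)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1L]; j <- cand[r, 2L]
    if (!used[i] && !used[j]) {
      keep[r] <- TRUE
      used[i] <- used[j] <- TRUE
      if (sum(keep) == n_plant) break
    }
  }
  planted <- cand[keep, , drop = FALSE]
  M <- matrix(sample(.AA20, cfg$N * cfg$L, replace = TRUE), cfg$N, cfg$L)
  for (r in seq_len(nrow(planted))) {
    i <- planted[r, 1L]; j <- planted[r, 2L]
    couple <- stats::runif(cfg$N) < cfg$coupling_strength
    t <- sample.int(4L, sum(couple), replace = TRUE)
    M[couple, i] <- .COUPLING_PATTERNS$first[t]
    M[couple, j] <- .COUPLING_PATTERNS$second[t]
  }
  .Random.seed_restore(old)
  cm <- matrix(0L, cfg$L, cfg$L)
  cm[planted] <- 1L
  cm[planted[, c(2L, 1L), drop = FALSE]] <- 1L
  diag(cm) <- 1L
  map <- structure(cm, mask = rep(FALSE, cfg$L), class = "contact_map")
  aln <- raw_alignment(apply(M, 1L, paste0, collapse = ""))
  list(alignment = aln, map = map, pairs = planted)
}

#' Toy coordinates with an analytically known contact map
#'
#' Residues are placed along a straight chain with fixed 3.8 Angstrom
#' spacing (the trivially self-avoiding curve), then the whole chain is
#' rigidly rotated and translated at random.  Distances are exactly
#' |i - j| * spacing, so with an 8 Angstrom cutoff the contacts are exactly
#' the pairs with |i - j| <= 2.
#'
#' @param L number of residues (>= 2).
#' @param seed RNG seed for the rigid motion.
#' @param spacing inter-residue spacing in Angstrom.
#' @return list with \code{coords} (L x 3), \code{map} (the analytic
#'   \code{contact_map} for an 8 Angstrom cutoff) and \code{spacing}.
#' @export
generate_toy_structure <- function(L, seed = 1L, spacing = 3.8) {
  if (L < 2L) stop("L must be >= 2")
  old <- .Random.seed_save()
  set.seed(seed)
  u <- stats::rnorm(3L)
  u <- u / sqrt(sum(u^2))
  origin <- stats::runif(3L, -50, 50)
  .Random.seed_restore(old)
  coords <- t(vapply(seq_len(L), function(i) origin + (i - 1) * spacing * u,
                     numeric(3L)))
  sep <- abs(outer(seq_len(L), seq_len(L), `-`))
  cm <- matrix(as.integer(sep * spacing < 8), L, L)
  map <- structure(cm, mask = rep(FALSE, L), class = "contact_map")
  list(coords = coords, map = map, spacing = spacing)
}

# ---- dataset + model-input helpers ------------------------------------------

#' Generate a labelled dataset of composition-signal MSAs
#'
#' Protein p uses seed \code{start_seed + p - 1}, so datasets are
#' reproducible and disjoint seeds give independent proteins.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param n number of proteins (default \code{cfg$n_proteins}).
#' @param task label task, see \code{\link{generate_ss_msa}}.
#' @param start_seed seed of the first protein.
#' @return named list of \code{\link{generate_ss_msa}} outputs.
#' @export
generate_ss_dataset <- function(cfg, n = cfg$n_proteins, task = "ss",
                                start_seed = cfg$seed) {
  out <- lapply(seq_len(n), function(p) {
    generate_ss_msa(cfg, task = task, seed = start_seed + p - 1L)
  })
  names(out) <- sprintf("synth_%s_%04d", task, seq_len(n))
  out
}

#' Generate a dataset of planted-covariation MSAs with contact maps
#'
#' @inheritParams generate_ss_dataset
#' @return named list of \code{\link{generate_contact_msa}} outputs.
#' @export
generate_contact_dataset <- function(cfg, n = cfg$n_proteins,
                                     start_seed = cfg$seed) {
  out <- lapply(seq_len(n), function(p) {
    generate_contact_msa(cfg, seed = start_seed + p - 1L)
  })
  names(out) <- sprintf("synth_cmap_%04d", seq_len(n))
  out
}

#' Encode a generated protein as SS/RSA training input
#'
#' @param gen one element of \code{\link{generate_ss_dataset}}.
#' @param depth_cap alignment depth cap Y.
#' @param width sliding window width.
#' @return list(x = window tensor (L, width, Y), y = integer labels 1..K).
#' @export
prepare_ss_protein <- function(gen, depth_cap, width = 31L) {
  enc <- encode_msa(gen$alignment, depth_cap = depth_cap)
  list(x = windows_tensor(extract_windows(enc, width)),
       y = match(gen$labels, gen$levels))
}

#' Encode a generated protein as CMAP training input
#'
#' @param gen one element of \code{\link{generate_contact_dataset}}.
#' @param depth_cap alignment depth cap Y.
#' @return list(x = encoded MSA, y = L x L 0/1 contact map).
#' @export
prepare_cmap_protein <- function(gen, depth_cap) {
  list(x = encode_msa(gen$alignment, depth_cap = depth_cap), y = gen$map)
}

#' Write a raw alignment as flat aligned FASTA
#'
#' @param aln a \code{\link{raw_alignment}}.
#' @param path output path.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "raw_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(aln$N)) {
    writeLines(c(paste0(">", aln$ids[i]), aln$sequences[i]), con)
  }
}
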