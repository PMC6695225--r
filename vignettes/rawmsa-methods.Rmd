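---
title: "Predicting protein structural features from raw alignments: models and methods"
author: "rawmsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein structural features from raw alignments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rawmsa)
```

## The idea

Most machine-learning predictors of protein structural features compress a
multiple sequence alignment (MSA) into a position-specific scoring matrix
before handing it to a model. That compression throws away everything the
profile cannot represent: which residues co-occur in the *same* homolog,
how the alignment is ordered, how deep it is. This package takes the
opposite route: the aligned sequences themselves are the input. Each
alignment cell is mapped to an integer in 1..25 (20 standard residues, the
ambiguity codes B, U, Z, X, and the gap), the integers are looked up in a
*learned embedding table* that maps every symbol to a continuous E-vector,
and the resulting tensor is processed end to end by a deep network trained
jointly with the embedding. Index 0 is reserved for padding and never
assigned to a residue, so zero-padded borders are exactly neutral.

Two architectures share this front end:

* **Per-residue (SS-RSA) network.** For each master-sequence residue a
  window of 31 alignment columns by Y sequences is cut (zero-padded at the
  termini and below shallow alignments). After embedding, a convolution
  whose filters are *column vectors* — they span only the alignment-depth
  axis, never neighbouring columns — is applied, followed by max pooling
  with the same 1 x W window, reducing the depth from Y to floor(Y/W). The
  pooled features feed a stack of two bidirectional LSTM layers along the
  31 window positions, then three fully connected layers ending in a
  softmax over 3 secondary-structure classes (H/E/C) or 4 or 2 relative
  solvent accessibility classes. Dropout follows each recurrent and dense
  layer.

* **Contact-map (CMAP) network.** The full-width MSA (L columns, depth cut
  at Y) passes through the same embedding and up to six column-wise
  conv/pool stages, producing per-position hidden features H of shape
  (L, F, S), where F is the pooled alignment depth and S the filter count.
  The pair expansion OP[i, j, f, s] = H[i, f, s] * H[j, f, s], reshaped to
  (L, L, F*S), turns per-position features into pair features; a trunk of
  square 2D convolutions (batch-normalised, ReLU, zero-padded so L x L is
  preserved) maps them to a 2-channel softmax giving each residue pair a
  contact probability. Because every layer is convolutional in L, a single
  trained model accepts proteins of any length.

The outer product is where covariation becomes visible: H at column i and
H at column j are computed from the *same rows* of the alignment, so the
product of depth-matched features responds when two columns vary together
across homologs — the signal that direct-coupling methods extract
analytically, here learned from the raw alignment.

## Why the column constraint matters

The column-wise convolution guarantees that information never spreads
across sequence positions before the recurrent stage (SS-RSA) or the pair
expansion (CMAP). This is asserted in the test suite by perturbation: for
random weight draws, changing one MSA column changes front-end activations
only at that column. It also means the front end is equivariant to the
row order of the alignment within a pooling block — but *not* across
blocks, which is why the package exposes `reorder_sequences()` (native
aligner order, BLOSUM62 similarity sort against the master, or a seeded
shuffle) to study order sensitivity.

## Labels

Ground truth comes from standard sources, parsed rather than recomputed:

* `parse_dssp()` reads DSSP output; the 8-class states collapse to 3 by
  the standard reduction {H, G, I} -> H, {E, B} -> E, rest -> C.
* Relative solvent accessibility is the DSSP absolute area divided by the
  residue's theoretical maximum area (Tien et al. 2013 values by default;
  the table is configuration and can be overridden), clipped at 1. The
  class thresholds are right-closed: [0, 0.04], (0.04, 0.25], (0.25, 0.5],
  (0.5, 1] for four classes and [0, 0.25], (0.25, 1] for two.
* Contacts are residue pairs whose C-beta atoms (C-alpha for glycine) lie
  *strictly* below 8 Angstrom; 8.00 exactly is a non-contact. Residues
  without coordinates are masked, never imputed, and masked pairs are
  excluded from evaluation.

## Training protocol

Training follows the one-protein-per-batch discipline: each optimisation
step consumes one protein — all of its windows, or its full contact map —
under RMSprop with sparse categorical cross-entropy. A random 10% of the
*proteins* (never individual windows, to avoid leakage between a protein's
own windows) is reserved for validation. After each epoch the validation
loss and accuracy are recorded; the checkpoint kept is the one with the
highest validation accuracy for per-residue models and the lowest
validation loss for contact models, which also drives optional
early stopping (`patience`). With fixed seeds, recorded histories are
bitwise repeatable on a given BLAS.

Evaluation uses Q3/Q4/Q2 (correct residues over total residues) and the
CASP convention for contacts: rank unmasked long-range pairs (sequence
separation strictly over 23) by predicted probability, take the top
floor(L/5) (minimum 1; ties broken by ascending pair index), and report
the fraction that are true contacts. Dataset numbers are unweighted means
over targets. Ensembling averages softmax outputs across models — and,
for contacts, across alignment sources — and picks the class with the
highest mean; contact maps are symmetrized by pair averaging
(P[i,j] + P[j,i]) / 2 *before* ranking, since the trunk convolutions are
free to break pair symmetry.

Homolog-safe splitting assigns chains to cross-validation folds whole
structural superfamily at a time: chains related to more than one
superfamily (or to none) are removed, then superfamilies are packed
largest-first into the currently smallest fold, with seed-shuffled ties.
No superfamily ever spans two folds; sequence-identity thresholds are
deliberately not used.

## The synthetic data generator

Desk-scale testing needs inputs whose learnable signal is known by
construction. Two generative models are provided:

* **Composition signal** (`generate_ss_msa`): a sticky Markov chain
  (stay probability 0.9) draws a hidden class per column; every sequence
  emits, per column, a residue from a class-specific 4-residue subset with
  probability 0.7 (uniform over the 20 standard residues otherwise), and
  non-master rows receive gaps at rate 0.05. The hidden path is the label.
  The class subsets echo helix/sheet/coil propensities (e.g. A, E, L, M
  for helix) and hydrophobicity for the accessibility states. The master
  row is produced by the same emission process but receives no gaps —
  master-gapped columns would not be indexable by master position.
* **Covariation signal** (`generate_contact_msa`): planted long-range
  pairs (5% of the pairs with separation over 23, capped at floor(L/2))
  jointly emit complementary charge pairs ((K,E), (R,D), (E,K), (D,R))
  with probability 0.8 per sequence; all other cells are uniform.
  Planted pairs are endpoint-disjoint: allowing shared endpoints would
  both dilute the planted coupling (overwrites) and leak covariation into
  non-planted pairs through shared partners, destroying the generator's
  defining property that planted pairs carry the top mutual information.
* `generate_toy_structure()` places residues on a straight chain with
  3.8 Angstrom spacing under a random rigid motion, so the distance matrix
  (|i - j| * 3.8) and hence the 8 Angstrom contact map are known
  analytically: contacts are exactly the pairs with |i - j| <= 2.

What the generator does *not* emulate: phylogenetic correlation between
sequences (rows are exchangeable given the hidden state), realistic indel
processes, alignment errors, and the long-tailed depth distribution of
real alignments. A model that learns these tasks demonstrably extracts
column composition and inter-column covariation from raw alignments — it
does not demonstrate real-protein accuracy, which requires training at
PDB scale on aligner-produced MSAs.

## Numerical and design choices

* **Vocabulary order** is not forced by the method; the package fixes the
  20 standard residues alphabetically (A=1 .. Y=20), then B=21, U=22,
  Z=23, X=24, gap=25. Letters outside the set (J, O, *) collapse to X.
* **Padding embedding**: index 0 has a learnable embedding row like any
  symbol; neutrality comes from the guarantee that real residues are
  always coded > 0.
* **Pooling remainder**: floor(Y/W) (valid pooling); depth exhausted to 0
  is rejected at hyperparameter validation.
* **Initialisation**: uniform fan-in scaling (Glorot-style) from a seeded
  RNG; all stochastic steps (init, splits, shuffling, dropout) derive from
  caller-supplied seeds, and helper functions restore the caller's RNG
  state.
* **Unstated head sizes**: the three fully connected layers are two hidden
  layers (200 units at full scale, exposed in `fc_units`) plus the class
  layer.
* **Ties**: argmax ties resolve to the lowest class index; checkpoint ties
  to the earliest epoch; ranking ties to the ascending pair index;
  BLOSUM62 sort ties keep the original row order. Gapped positions are
  skipped (not penalised) in the BLOSUM62 score, and symbols absent from
  the matrix score as X.
* **Optimisation**: RMSprop with rho 0.9, epsilon 1e-7, default learning
  rate 1e-3.

## Desk-scale problem sizes

The test suite and the acceptance script train deliberately small
configurations chosen so the whole pipeline — generation, training,
prediction, evaluation — exercises every code path on a single CPU:

* per-residue: 40 training + 10 held-out proteins of length 60 with 200
  sequences each (2,400 training residues), model E=8, Y=20, 16 LSTM units
  per direction, 5 epochs. This reaches held-out Q3 around 0.93-0.95
  against a ~0.35-0.40 majority baseline.
* contacts: 30 training + 8 held-out proteins, model E=8, Y=16, pool
  window 2, three trunk layers of 16 filters, up to 25 epochs with
  patience 10. The small pool window is deliberate: presence-style
  features over small row blocks saturate less, so depth-matched products
  discriminate matched from unmatched column pairs more sharply. Held-out
  top-L/5 long-range precision lands far above the random-ranking
  baseline (the targets' long-range contact density, ~4%).

The published full-scale settings (E up to 30, Y up to 1000, 350 LSTM
units, 6-20 trunk layers, PDB-wide training) are expressible with the same
`ss_rsa_hyperparams()` / `cmap_hyperparams()` containers but are outside
what this package's tests run.

## Known limitations

* Training is CPU-bound, single-threaded R; it is an exact, readable
  reference implementation of the method, not a performance-tuned one.
* Distances are not predicted, only binary contacts; 8-class secondary
  structure is reduced to 3 before modelling.
* A3M support flattens insertions; full Stockholm parsing is out of scope
  (convert to FASTA first).
* The BLOSUM62 sort scores each sequence against the master only, as the
  reordering study requires — it is not a general similarity clustering.
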