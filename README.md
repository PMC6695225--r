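# rawmsa

End-to-end prediction of protein structural features — per-residue
secondary structure (SS), relative solvent accessibility (RSA) and
inter-residue contact maps — **directly from raw multiple sequence
alignments**, with no sequence profile (PSSM) in between.

Profile compression averages away everything a column-frequency matrix
cannot hold: which residues co-occur in the *same* homolog, alignment
order, alignment depth. This package instead integer-codes the aligned
sequences themselves (residues → 1..25, with 0 reserved for padding), maps
each symbol through a **learned embedding** into a continuous E-dimensional
space, and trains deep networks on that tensor end to end. It is written
for structural bioinformaticians who want a complete, exact, desk-scale
reference implementation of the approach in R — every layer, including the
backward passes, is implemented in the package and verified against
numerical gradients and brute-force oracles in the test suite.

## The two architectures

**Per-residue (SS-RSA).** For master residue *i*, a 31-column × Y-sequence
window (zero-padded at termini and below shallow alignments) is embedded
and passed through a *column-wise* convolution + max-pooling stage — the
1×W filters span only the alignment-depth axis, so positions never mix —
reducing the depth Y to ⌊Y/W⌋. Two stacked bidirectional LSTM layers run
along the 31 positions, and three fully connected layers end in a softmax
over 3 SS classes (H/E/C) or 4/2 RSA classes.

**Contact map (CMAP).** The full-width MSA passes through the same front
end, giving per-position hidden features H of shape (L, F, S). The outer
product

    OP[i, j, f, s] = H[i, f, s] · H[j, f, s]   →  reshaped to L × L × (F·S)

lifts them to pair features, and a trunk of square 2D convolutions
(batch-normalised, ReLU, zero-padded to preserve L × L) ends in a
2-channel softmax: a contact probability for every residue pair. Because H
at columns *i* and *j* is computed from the same alignment rows, the
depth-matched products respond to inter-column covariation — the contact
signal. The network is fully convolutional in L, so one model serves
proteins of any length.

Training follows the one-protein-per-batch protocol (RMSprop, sparse
categorical cross-entropy, per-protein 10% validation split,
best-validation checkpoint selection), evaluation uses Q3/Q4/Q2 and the
CASP top-L/5 long-range (separation > 23) contact precision, ensembles
average softmax outputs over models and alignment sources, and
train/test separation is enforced by superfamily-disjoint fold splitting.
Labels come from parsed DSSP output (SS8→SS3, MaxASA-normalised RSA with
right-closed thresholds) and PDB coordinates (Cβ, Cα for Gly, strict 8 Å).

## Worked example

```r
library(rawmsa)

## read an A3M alignment (lowercase insertions are flattened away)
aln <- read_alignment(system.file("extdata", "synthetic_example.a3m",
                                  package = "rawmsa"), format = "a3m")
aln
#> raw_alignment: 4 sequences, master length 20

## integer-code it with a depth cap of 8 (zero rows pad the bottom)
enc <- encode_msa(aln, depth_cap = 8)
enc
#> encoded_msa: depth Y=8 x length L=20 (N=4 sequences)
unclass(enc)[1:4, 1:8]
#>      [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8]
#> [1,]   11    9   18   10    8   17    6    1
#> [2,]   11    9   18   10    8   17    6   16
#> [3,]   11   15   18   25    8   17    6    1
#> [4,]   11    9    8   10    8   17    6    1

## one sliding window per master residue
w <- extract_windows(enc)
length(w); dim(w[[1]])
#> 20 windows of 8 x 31

## ground-truth labels from DSSP output
dssp <- parse_dssp(system.file("extdata", "synthetic_toy.dssp",
                               package = "rawmsa"))
lab <- structure_labels(dssp)
head(data.frame(residue = lab$residue, ss3 = lab$ss3,
                rsa = round(lab$rsa, 2), rsa4 = lab$rsa4))
#>   residue ss3  rsa                rsa4
#> 1       A   H 0.08     PartiallyBuried
#> 2       K   H 0.51          Accessible
#> 3       G   C 0.38 PartiallyAccessible
#> 4       W   C 0.00              Buried
#> 5       V   E 0.02              Buried
#> 6       L   E 0.03              Buried

## a native contact map from PDB coordinates (Cbeta; Calpha for Gly)
xyz <- pdb_representative_coords(system.file("extdata", "synthetic_toy.pdb",
                                             package = "rawmsa"))
cm <- contact_map_from_coords(xyz)
sum(unclass(cm)[upper.tri(unclass(cm))])
#> [1] 21   # on this 3.8 A toy chain: exactly the pairs with |i-j| <= 2
```

Row 1 is the master sequence (M=11, K=9, V=18, L=10, ...); the gap in hit 2
codes as 25. From here, `build_ss_rsa_model()` / `build_cmap_model()`
construct networks, `train_model()` trains them one protein per batch, and
`predict_ss_rsa()` / `predict_contacts()` / `predict_contacts_ensemble()`
produce class probabilities. `generate_ss_dataset()` and
`generate_contact_dataset()` provide synthetic alignments with planted,
analytically known signal to train against; see the methods vignette
(`vignettes/rawmsa-methods.Rmd`) for the generative models, the
architecture, and every numerical convention.

A thin CLI wraps the common file-level operations:

```sh
rawmsa synth  --task ss --n 10 --L 60 --N 200 --seed 7 --out fixtures/
rawmsa encode --in aln.a3m --format a3m --depth 100 --order native --out msa.txt
rawmsa evaluate --task cmap --pred preds/ --truth native/ --report report.tsv
```

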