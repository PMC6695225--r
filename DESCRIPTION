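Package: rawmsa
Title: End-to-End Prediction of Protein Structural Features from Raw
    Multiple Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-residue secondary structure, relative solvent
    accessibility and inter-residue contact maps directly from raw multiple
    sequence alignments, without compressing the alignment into a sequence
    profile.  Alignments are integer-coded, mapped into a learned continuous
    embedding space and processed by column-wise convolutional stages; a
    recurrent head labels individual residues while an outer-product pair
    expansion followed by a 2D convolutional trunk predicts full contact
    maps.  Includes DSSP/PDB label generation, superfamily-disjoint dataset
    splitting, softmax-averaging ensembles, CASP-style top-L/5 long-range
    contact evaluation, and a synthetic-data generator with planted
    column-composition and covariation signals for desk-scale testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
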