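ATOM      1  CA  ALA A   1       4.296  32.294  47.150  1.00  0.00           C
ATOM      2  CB  ALA A   1       2.796  30.794  45.650  1.00  0.00           C
ATOM      3  CA  LYS A   2       2.737  34.860  44.822  1.00  0.00           C
ATOM      4  CB  LYS A   2       1.237  33.360  43.322  1.00  0.00           C
ATOM      5  CA  GLY A   3      -0.322  35.927  40.994  1.00  0.00           C
ATOM      6  CA  TRP A   4      -0.382  39.994  40.166  1.00  0.00           C
ATOM      7  CB  TRP A   4      -1.882  38.494  38.666  1.00  0.00           C
ATOM      8  CA  VAL A   5      -1.941  42.561  37.838  1.00  0.00           C
ATOM      9  CB  VAL A   5      -3.441  41.061  36.338  1.00  0.00           C
ATOM     10  CA  LEU A   6      -3.500  45.128  35.510  1.00  0.00           C
ATOM     11  CB  LEU A   6      -5.000  43.628  34.010  1.00  0.00           C
ATOM     12  CA  GLU A   7      -5.059  47.695  33.182  1.00  0.00           C
ATOM     13  CB  GLU A   7      -6.559  46.195  31.682  1.00  0.00           C
ATOM     14  CA  GLU A   8      -6.618  50.262  30.854  1.00  0.00           C
ATOM     15  CB  GLU A   8      -8.118  48.762  29.354  1.00  0.00           C
ATOM     16  CA  ARG A   9      -8.177  52.829  28.526  1.00  0.00           C
ATOM     17  CB  ARG A   9      -9.677  51.329  27.026  1.00  0.00           C
ATOM     18  CA  PHE A  10      -9.737  55.396  26.198  1.00  0.00           C
ATOM     19  CB  PHE A  10     -11.237  53.896  24.698  1.00  0.00           C
ATOM     20  CA  SER A  11     -11.296  57.963  23.870  1.00  0.00           C
ATOM     21  CB  SER A  11     -12.796  56.463  22.370  1.00  0.00           C
ATOM     22  CA  THR A  12     -12.855  60.530  21.542  1.00  0.00           C
ATOM     23  CB  THR A  12     -14.355  59.030  20.042  1.00  0.00           C
END
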