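==== Secondary Structure Definition by the program DSSP (synthetic example) ====
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA
    1    1 A A  H                   10
    2    2 A K  H                  120
    3    3 A G  T                   40
    4    4 A W                       0
    5    5 A V  E                    3
    6    6 A L  E                    7
    7    7 A E  S                  150
    8    8 A E  H                   90
    9    9 A R  G                  200
   10   10 A F  B                   12
   11   11 A S  T                   60
   12   12 A T  C                   80
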