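>seq1
VIGYDQAAELMSNVPRVGNNPGPPIGGSICSNGGDGGDYP
>seq2
KTQH--HM-FLPWSMNPGPRFKPS-YDSPFNSHARFKN-K
>seq3
WSVDHAMMALNSGNGSNWNPVGSSY-FGNNSSNPNWGFGC
>seq4
I-YMPCPELGMGNGA--GGNHSSCPPSNPSGPS-NNMNFN
>seq5
I-MNYLGEMAAWGLSGNGNGTGHNNNNRSGQT-PI--GGS
>seq6
IVYVYLEAWEENG-GNPSLSPWGGSHNHH-GSNSGSEGGD
>seq7
YHSWVLLLELPWGVNNGQSSNNPSNSEPP-SPPTMAGSPS
>seq8
IWIWWMELAAK-NPFPSNNNVSPPSHIGSGNYVPQPGNSN
>seq9
YYWVQLMLMRNIRSNPNSNSSHSNNFPCPG-DGICNPGSS
>seq10
IIYYIHEALAAGHGHGP-LYG-SIFIPNPPEGNYKGCNKS
>seq11
VSVIVAE-EEYKSFSGWGPKGNYEPYNSWSSGCSDGPSGD
>seq12
YGWYIAEAAALSMPGNSLGPSPGSIVGPNGP-P-NSNNVN
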