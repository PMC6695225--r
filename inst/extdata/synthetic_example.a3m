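>master
MKVLITGAGSGIGKEAALLF
>hit1
MKVLvITGSGSGIGREAAmLLF
>hit2
MRV-ITGAGS-GIGKESALF
>hit3
MKILITGAGAGIGQEAALaLF
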