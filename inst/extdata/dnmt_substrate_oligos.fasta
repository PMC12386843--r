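>CG_substrate DNA methyltransferase assay substrate, CG context
CGACGACGTTAAAATACGAAAT
>CNG_substrate DNA methyltransferase assay substrate, CNG context
AAACCGAACCGAAAAACCG
>CNN_substrate DNA methyltransferase assay substrate, CNN context
TACAACCAAAAAAACCTCTTC
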