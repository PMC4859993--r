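>Gly synthetic stand-in 3'-terminal 18-mer (CCA tail)
TGGTGCGGGAATTCACCA
>Pro synthetic stand-in 3'-terminal 18-mer (CCA tail)
ACCTAGGATACTGCGCCA
>Gln synthetic stand-in 3'-terminal 18-mer (CCA tail)
GATCCATTGCAGTAGCCA
>Met synthetic stand-in 3'-terminal 18-mer (CCA tail)
CCATAACGGTTAGTACCA
>Thr synthetic stand-in 3'-terminal 18-mer (CCA tail)
TTAGCGTCAACGGATCCA
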