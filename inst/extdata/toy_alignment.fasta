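>AA0001
CCTATTATCTACCTGCAGAGGACAGTGCCCAGGCTACGCTCGCATTGTTATATAAATCATCGATCTCACAAATGTCCATC
>AA0002
CCTATTATCTACCTGCAGAGGACAGTGGCCAGGCTACGCTCGCATTATTATATAAATCATCTATCTCACGAATGTCCATC
>AA0003
CCTATTATCTACCTGCAGAGGACAGTGGCCAAGCTACGCTCGCATTGTTATATAAATCATCGATCTCACGAATGTCCTTC
>AA0004
CCTATTATCTACCTGCAGAGGACAGTGGCCAGGCTACGCTCGAATTGTTATATAATTCATCGATCTCACGAATGTCCATC
>AA0005
CCCATTATCTACCTGCAGAGGACAGTGGCCAGGCTACGCTCGCATTGTTATATAAATCATCGATCTCGCGAATGTCCATC
>AA0006
CCTATTATCTACCTGCAGAGGACAGTGCCCAGGCTACGCTCGCATTGTTATATAAATCATCGATCTCACAAATGTCCATC
>AA0007
CCTATTATCTACCTGCAGAGGACAGTGGCCAAGCTACGCTCGCATTGTTATATAAATCATCGATCTCACGAATGTCCTTC
>AA0008
CCTATTATCTACCTGCAGAGGACAGTGCCCAGGCTACGCTCGCATTGTTATATAAATCATCGATCTCACAAATGTCCATC
>AB0001
CCTATTATCTACCTGCAGAGGACAGTGGCCAGGCTACGCTCGAATTGTTATATAATTCATCGATCTCACGAATGTCCATC
>AB0002
CCTATTATCTAACTGCAGAGGACAGTGGCCAGGCTACGCTCGCATTGTTATATAAATCATCGATCTCACGAGTGTCCATC
>AB0003
CCTATTATCTACCTGCAGAGGACAGTGGCCAAGCTACGCTCGCATTGTTATATAAATCATCGATCTCACGAATGTCCTTC
>AB0004
CCTATTATCTAACTGCAGAGGACAGTGGCCAGGCTACGCTCGCATTGTTATATAAATCATCGATCTCACGAGTGTCCATC
>AB0005
CCTATTATCTACCTGCAGAGGACAGTGGCCAGGCTACGCTCGAATTGTTATATAATTCATCGATCTCACGAATGTCCATC
>AB0006
CCTATTATCTAACTGCAGAGGACAGTGGCCAGGCTACGCTCGCATTGTTATATAAATCATCGATCTCACGAGTGTCCATC
>AB0007
CCTATTATCTACCTGCAGAGGACAGTGGCCAGGCTACGCTCGAATTGTTATATAATTCATCGATCTCACGAATGTCCATC
>AB0008
CCTATTATCTACCTGCAGAGGACAGTGGCCAGGCTACGCTCGAATTGTTATATAATTCATCGATCTCACGAATGTCCATC
>AC0001
CCTATAATCTACCCGGAGAGAACAGTGGCCGGACTACGCTCGCATTGTCATGTAAATCCTCGATCTCACGAATGCCCATC
>AC0002
CCTATAATCTACCCGGAAAGAACAGTGGCCGGGCTACGCTCGCATTGTTATGTAAATCCTCGATCTCACGAATGCCAATC
>AC0003
CCTATAAGCTACCCGGCGAGAACAGTGGCCGGGCTACGCTCGCATTGTTATGTAAATCCTCGATCTCACGAATGCCCATC
>AC0004
CCTATAATCTACCCGGAGAGAACAGTGGCCGGACTACGCTCGCATTGTCATGTAAATCCTCGATCTCACGAATGCCCATC
>AC0005
CCTATAATCTACCCGGAGAGAACAGTGGCCGGACTACGCTCGCATTGTCATGTAAATCCTCGATCTCACGAATGCCCATC
>AC0006
CCTATAATCTACCCGGAGAGAACAGTGGCCGGACTACGCTCGCATTGTCATGTAAATCCTCGATCTCACGAATGCCCATC
>AC0007
CCTATAATCTACCCGGAGAGAACAGTGGCCGGACTACGCTCGCATTGTCATGTAAATCCTCGATCTCACGAATGCCCATC
>AC0008
CCTATAATCTACCCGGAGAGAACAGTGGCCGGACTACGCTCGCATTGTCATGTAAATCCTCGATCTCACGAATGCCCATC
>AD0001
CCTATAATCTACCCGGAGAGAACAGTGGCCGGGCTACGCTCGCATTGTTATGTAAATCCTCGATGTGACGAATGCCCATC
>AD0002
CCTATAAGCTACCCGGCGAGAACAGTGGCCGGGCTACGCTCGCATTGTTATGTAAATCCTCGATCTCACGAATGCCCATC
>AD0003
CCTATAATCTACCCGGAGAGAACTGTGGCCGGGCTAAGCTCGCATTGTTATGTAAATCCTCGATCTCACGAATGCCCATC
>AD0004
CCTATAGTCTACCCGGAGAGAACAGTGGCCGGGCTACGCTCGCAGTGTTATGTAAATCCTCGATCTCACGAATGCCCATC
>AD0005
CCTATAATCTACCCGGAGAGAACAGTGGCCGGGCTACGCTCGCATTGTTATGTAAATCCTCGATGTGACGAATGCCCATC
>AD0006
CCTATAAGCTACCCGGCGAGAACAGTGGCCGGGCTACGCTCGCATTGTTATGTAAATCCTCGATCTCACGAATGCCCATC
>AD0007
CCTATAAGCTACCCGGCGAGAACAGTGGCCGGGCTACGCTCGCATTGTTATGTAAATCCTCGATCTCACGAATGCCCATC
>AD0008
CCTATAATCTACCCGGAGAGAACAGTGGCCGGGCTACGCTCGCATTGTTATGTAAATCCTCGATGTGACGAATGCCCATC
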