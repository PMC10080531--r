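8
ethane, staggered, r_cc 1.512 r_ch 1.153
C        0.0000000000       0.0000000000      -0.7560000000
C        0.0000000000       0.0000000000       0.7560000000
H        1.0870588249       0.0000000000      -1.1403333333
H       -0.5435294125       0.9414205578      -1.1403333333
H       -0.5435294125      -0.9414205578      -1.1403333333
H        0.5435294125       0.9414205578       1.1403333333
H       -1.0870588249       0.0000000000       1.1403333333
H        0.5435294125      -0.9414205578       1.1403333333
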