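6
(H2)3 alternating chain
H        0.0000000000       0.0000000000       0.0000000000
H        0.0000000000       0.0000000000       0.7414410000
H        0.0000000000       0.0000000000       2.0643840000
H        0.0000000000       0.0000000000       2.8058250000
H        0.0000000000       0.0000000000       4.1287680000
H        0.0000000000       0.0000000000       4.8702090000
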