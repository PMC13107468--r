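6
idealized planar ethylene monomer
C        -0.6665000000       0.0000000000       0.0000000000
C         0.6665000000       0.0000000000       0.0000000000
H        -1.2115000000       0.9440000000       0.0000000000
H        -1.2115000000      -0.9440000000       0.0000000000
H         1.2115000000       0.9440000000       0.0000000000
H         1.2115000000      -0.9440000000       0.0000000000
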