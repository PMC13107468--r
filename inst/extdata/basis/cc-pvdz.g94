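! cc-pVDZ (H, He, C), spherical harmonics, G94 text format.
****
H     0
S   4   1.00
     13.0100000              0.0196850
      1.9620000              0.1379770
      0.4446000              0.4781480
      0.1220000              0.5012400
S   1   1.00
      0.1220000              1.0000000
P   1   1.00
      0.7270000              1.0000000
****
He     0
S   4   1.00
     38.3600000              0.0238090
      5.7700000              0.1548910
      1.2400000              0.4699870
      0.2976000              0.5130270
S   1   1.00
      0.2976000              1.0000000
P   1   1.00
      1.2750000              1.0000000
****
C     0
S   9   1.00
   6665.0000000              0.0006920
   1000.0000000              0.0053290
    228.0000000              0.0270770
     64.7100000              0.1017180
     21.0600000              0.2747400
      7.4950000              0.4485640
      2.7970000              0.2850740
      0.5215000              0.0152040
      0.1596000             -0.0031910
S   9   1.00
   6665.0000000             -0.0001460
   1000.0000000             -0.0011540
    228.0000000             -0.0057250
     64.7100000             -0.0233120
     21.0600000             -0.0639550
      7.4950000             -0.1499810
      2.7970000             -0.1272620
      0.5215000              0.5445290
      0.1596000              0.5804960
S   1   1.00
      0.1596000              1.0000000
P   4   1.00
      9.4390000              0.0381090
      2.0020000              0.2094800
      0.5456000              0.5085570
      0.1517000              0.4688420
P   1   1.00
      0.1517000              1.0000000
D   1   1.00
      0.5500000              1.0000000
****
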