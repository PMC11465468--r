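12
benzene, literature geometry r(CC)=1.397 r(CH)=1.084
C      1.3970000000    0.0000000000    0.0000000000
C      0.6985000000    1.2098374891    0.0000000000
C     -0.6985000000    1.2098374891    0.0000000000
C     -1.3970000000    0.0000000000    0.0000000000
C     -0.6985000000   -1.2098374891    0.0000000000
C      0.6985000000   -1.2098374891    0.0000000000
H      2.4810000000    0.0000000000    0.0000000000
H      1.2405000000    2.1486090268    0.0000000000
H     -1.2405000000    2.1486090268    0.0000000000
H     -2.4810000000    0.0000000000    0.0000000000
H     -1.2405000000   -2.1486090268    0.0000000000
H      1.2405000000   -2.1486090268    0.0000000000
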