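6
ethylene, literature geometry r(CC)=1.339 r(CH)=1.086 HCC=121.2
C      0.0000000000    0.0000000000    0.6695000000
C      0.0000000000    0.0000000000   -0.6695000000
H      0.0000000000    0.9289255865    1.2320773322
H      0.0000000000   -0.9289255865    1.2320773322
H      0.0000000000    0.9289255865   -1.2320773322
H      0.0000000000   -0.9289255865   -1.2320773322
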