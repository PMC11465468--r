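4
formaldehyde, literature geometry r(CO)=1.203 r(CH)=1.099 HCO=121.9
C      0.0000000000    0.0000000000    0.0000000000
O      0.0000000000    0.0000000000    1.2030000000
H      0.0000000000    0.9330198847   -0.5807537299
H      0.0000000000   -0.9330198847   -0.5807537299
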