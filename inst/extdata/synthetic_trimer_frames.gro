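synthetic 3-atom molecule, frame 1, t= 0.000
    3
    1MOL     OW    1   1.000   1.000   1.000
    1MOL    HW1    2   1.200   1.000   1.000
    1MOL    HW2    3   1.000   1.400   1.000
   5.00000   5.00000   5.00000
synthetic 3-atom molecule, frame 2, t= 5.000
    3
    1MOL     OW    1   1.100   1.000   1.000
    1MOL    HW1    2   1.300   1.000   1.000
    1MOL    HW2    3   1.100   1.400   1.000
   5.00000   5.00000   5.00000
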