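# effect-compartment and Hill constants of the same subject
ke3_over_V3: 0.02
T: 15
D0: 0.279
Dmax: 0.31
Dc50: 0.38
N: 8
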