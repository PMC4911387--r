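# plasma constants of a fluctuating (group 2) subject [L/min]
k21: 1.26
k12: 1.77
ketot: 0.58
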