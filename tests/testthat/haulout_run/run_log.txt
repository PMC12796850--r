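hauloutnet 0.1.0 | seed 1 | conventions: cost=inverse_dc_weight norm=pairs
events: 23 raw, 23 after merging (<600 s gaps)
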