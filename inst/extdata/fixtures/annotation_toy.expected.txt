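oracle: by construction
8 samples, contrast Knockout with levels control (n=4) / mutant (n=4)
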