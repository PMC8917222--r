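oracle: closed-form pooled-variance t, checked against the t CDF
sp^2 = 1, se = sqrt(2/3) = 0.8165, t = -1.2247, df = 4, p = 0.2878
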