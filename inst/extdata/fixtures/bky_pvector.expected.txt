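oracle: hand-traced two-stage step-up at q = 0.05
stage-1 level q/(1+q) = 0.047619 -> r1 = 2 rejections
stage-2 level 0.047619 * 4 / 2 = 0.095238 -> discoveries {0.001, 0.01}
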