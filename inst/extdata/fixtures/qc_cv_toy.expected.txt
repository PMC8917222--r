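oracle: CV% = 100 * sd/mean with the n-1 standard deviation
LIP_OK: mean 100, sd 10 -> CV 10% -> retained (< 30)
LIP_BAD: mean 100, sd 90 -> CV 90% -> removed
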