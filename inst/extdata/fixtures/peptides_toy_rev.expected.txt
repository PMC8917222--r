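oracle: hand parse; row EEEEK is a reverse decoy (Reverse = '+')
default read drops the decoy: 6 records remain, flagged copy has 8
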