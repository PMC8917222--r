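Sequence	Proteins	Reverse	Potential contaminant	Intensity A	Intensity B
AAAAK	P1			1024	2048
CCCCK	P1;P2			512	0
DDDDK	P3			256	128
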