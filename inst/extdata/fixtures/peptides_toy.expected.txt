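oracle: direct hand parse of the 3-row table
records: 6 (3 peptides x 2 samples), 0 flagged
protein group of CCCCK kept verbatim as 'P1;P2'
empty/zero intensity cells parse as 0 (not detected)
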