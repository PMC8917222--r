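oracle: brute-force enumeration of the imputation rule
pool for missing condition B = {6..15}, N = 10, ceil(0.1*10) = 1
imputation value = mean of 1 smallest = 6.0
peptide FCs = {10-6, 12-6} = {4, 6}; protein log2 FC = median = 5.0
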