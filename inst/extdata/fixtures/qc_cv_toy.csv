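lipid_id,replicate,ratio
LIP_OK,1,90
LIP_OK,2,100
LIP_OK,3,110
LIP_BAD,1,10
LIP_BAD,2,100
LIP_BAD,3,190
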