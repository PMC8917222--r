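group,value
a,1
a,2
a,3
b,2
b,3
b,4
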