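sample_id,Knockout
ctrl_1,control
ctrl_2,control
ctrl_3,control
ctrl_4,control
mut_1,mutant
mut_2,mutant
mut_3,mutant
mut_4,mutant
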