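peptide_id,condition,mean_t
obs_pep1,A,10
obs_pep2,A,12
pool_pep1,B,6
pool_pep2,B,7
pool_pep3,B,8
pool_pep4,B,9
pool_pep5,B,10
pool_pep6,B,11
pool_pep7,B,12
pool_pep8,B,13
pool_pep9,B,14
pool_pep10,B,15
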