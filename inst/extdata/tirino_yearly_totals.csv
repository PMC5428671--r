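year,total_individuals,n_samples
1997,992,8
2005,2750,8
2012,910,8
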