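key	value
n_loci	1113
n_hd	437
n_cyclase	1028
csx1_solo	284
csx1_cooccurring	127
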