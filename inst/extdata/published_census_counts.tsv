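family	n_loci
Csx1	411
Can1-2	143
Cami1	135
Csm6	55
CorA	53
Cam1	52
NucC	35
CalpL	17
Csx23	4
SAVED-CHAT	3
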