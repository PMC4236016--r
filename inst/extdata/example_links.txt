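protein1 protein2 combined_score
9606.ENSP0001 9606.ENSP0002 999
9606.ENSP0001 9606.ENSP0003 982
9606.ENSP0002 9606.ENSP0003 975
9606.ENSP0003 9606.ENSP0004 507
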