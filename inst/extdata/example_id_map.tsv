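gene	protein
RPL13A	9606.ENSP0001
RPS6	9606.ENSP0002
EEF1A1	9606.ENSP0003
MYC	9606.ENSP0004
CDKN1A	9606.ENSP0005
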