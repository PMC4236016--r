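Gene,K,E,L,BP
RPL13A,1850.2,1799.6,1833.1,1810.4
RPS6,2104.7,2088.3,2121.9,2095.5
EEF1A1,2950.1,2902.8,2931.4,2918.2
MYC,84.3,162.7,409.5,455.1
CDKN1A,310.6,241.2,96.8,88.4
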