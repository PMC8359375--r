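solution,round,ec50
TS1,1,NMT
TS1,2,40
TS2,1,NMT
TS2,2,24
TS3,1,NMT
TS3,2,NMT
TS4,1,89
TS4,2,92
TS5,1,NMT
TS6,1,NMT
TS6,2,NMT
TS7,1,NMT
TS7,2,NMT
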