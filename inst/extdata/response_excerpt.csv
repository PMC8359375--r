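species,solution,round,end_survival,difference,c1,c2,c3,c4,c5,printed_score,printed_judgment
Gaimardia trapesina,TS1,1,0,78,1,1,1,0,1,93,Response
Gaimardia trapesina,TS2,1,0,78,1,1,1,1,1,100,Response
Gaimardia trapesina,TS3,1,96,-18,0,0,0,0,0,0,NoResponse
Gaimardia trapesina,TS4,1,85,-7,0,0,0.5,0,0,9,NoResponse
Gaimardia trapesina,TS5,1,61,18,1,0.5,1,0,0,68,Response
Gaimardia trapesina,TS6,1,0,78,1,1,1,1,1,100,Response
Gaimardia trapesina,TS7,1,96,-18,0,0,0,0,0,0,NoResponse
Parawaldeckia kidderi,TS1,2,78,2,0,0,1,0,0,18,NoResponse
Parawaldeckia kidderi,TS2,2,88,-8,0,0,0,0,0,0,NoResponse
Parawaldeckia kidderi,TS3,2,78,2,0,0,1,0,0,18,NoResponse
Parawaldeckia kidderi,TS4,2,88,-8,0,0,0,0,0,0,NoResponse
Parawaldeckia kidderi,TS6,2,90,-10,0,0,0,0,0,0,NoResponse
Parawaldeckia kidderi,TS7,2,70,10,0.5,0,1,0,0.5,41,NoResponse
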