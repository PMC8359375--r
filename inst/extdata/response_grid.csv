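unit,type,solution,round,label
Paramoera sp.,species,TS1,1,NoResponse
Paramoera sp.,species,TS2,1,NoResponse
Paramoera sp.,species,TS3,1,NoResponse
Paramoera sp.,species,TS4,1,NoResponse
Paramoera sp.,species,TS5,1,NoResponse
Paramoera sp.,species,TS6,1,NoResponse
Paramoera sp.,species,TS7,1,NoResponse
Parawaldeckia kidderi,species,TS1,2,NoResponse
Parawaldeckia kidderi,species,TS2,2,NoResponse
Parawaldeckia kidderi,species,TS3,2,NoResponse
Parawaldeckia kidderi,species,TS4,2,NoResponse
Parawaldeckia kidderi,species,TS6,2,NoResponse
Parawaldeckia kidderi,species,TS7,2,NoResponse
Exosphaeroma gigas,species,TS1,1,Response
Exosphaeroma gigas,species,TS2,1,NoResponse
Exosphaeroma gigas,species,TS3,1,NoResponse
Exosphaeroma gigas,species,TS4,1,NoResponse
Exosphaeroma gigas,species,TS5,1,NoResponse
Exosphaeroma gigas,species,TS6,1,Response
Exosphaeroma gigas,species,TS7,1,NoResponse
Zaus sp.,species,TS1,1,Response
Zaus sp.,species,TS2,1,Response
Zaus sp.,species,TS3,1,NoResponse
Zaus sp.,species,TS4,1,Response
Zaus sp.,species,TS5,1,Response
Zaus sp.,species,TS6,1,Response
Zaus sp.,species,TS7,1,NoResponse
Zaus sp.,species,TS1,2,Response
Zaus sp.,species,TS2,2,Response
Zaus sp.,species,TS3,2,NoResponse
Zaus sp.,species,TS4,2,Response
Zaus sp.,species,TS6,2,Response
Zaus sp.,species,TS7,2,NoResponse
Tigriopus angulatus,species,TS1,1,NoResponse
Tigriopus angulatus,species,TS2,1,NoResponse
Tigriopus angulatus,species,TS3,1,NoResponse
Tigriopus angulatus,species,TS4,1,Response
Tigriopus angulatus,species,TS5,1,NoResponse
Tigriopus angulatus,species,TS6,1,NoResponse
Tigriopus angulatus,species,TS7,1,NoResponse
Tigriopus angulatus,species,TS1,2,NoResponse
Tigriopus angulatus,species,TS2,2,Response
Tigriopus angulatus,species,TS3,2,NoResponse
Tigriopus angulatus,species,TS4,2,Response
Tigriopus angulatus,species,TS6,2,NoResponse
Tigriopus angulatus,species,TS7,2,Response
Laevilitorina caliginosa,species,TS1,1,NoResponse
Laevilitorina caliginosa,species,TS2,1,NoResponse
Laevilitorina caliginosa,species,TS3,1,NoResponse
Laevilitorina caliginosa,species,TS4,1,NoResponse
Laevilitorina caliginosa,species,TS5,1,NoResponse
Laevilitorina caliginosa,species,TS6,1,NoResponse
Laevilitorina caliginosa,species,TS7,1,NoResponse
Laevilitorina caliginosa,species,TS1,2,Response
Laevilitorina caliginosa,species,TS2,2,Response
Laevilitorina caliginosa,species,TS3,2,NoResponse
Laevilitorina caliginosa,species,TS4,2,NoResponse
Laevilitorina caliginosa,species,TS6,2,NoResponse
Laevilitorina caliginosa,species,TS7,2,NoResponse
Macquariella hamiltoni,species,TS1,1,Response
Macquariella hamiltoni,species,TS2,1,Response
Macquariella hamiltoni,species,TS3,1,NoResponse
Macquariella hamiltoni,species,TS4,1,Response
Macquariella hamiltoni,species,TS5,1,Response
Macquariella hamiltoni,species,TS6,1,Response
Macquariella hamiltoni,species,TS7,1,NoResponse
Macquariella hamiltoni,species,TS1,2,Response
Macquariella hamiltoni,species,TS2,2,Response
Macquariella hamiltoni,species,TS3,2,NoResponse
Macquariella hamiltoni,species,TS4,2,Response
Macquariella hamiltoni,species,TS6,2,Response
Macquariella hamiltoni,species,TS7,2,NoResponse
Gaimardia trapesina,species,TS1,1,Response
Gaimardia trapesina,species,TS2,1,Response
Gaimardia trapesina,species,TS3,1,NoResponse
Gaimardia trapesina,species,TS4,1,NoResponse
Gaimardia trapesina,species,TS5,1,Response
Gaimardia trapesina,species,TS6,1,Response
Gaimardia trapesina,species,TS7,1,NoResponse
Gaimardia trapesina,species,TS1,2,Response
Gaimardia trapesina,species,TS2,2,Response
Gaimardia trapesina,species,TS3,2,NoResponse
Gaimardia trapesina,species,TS4,2,NoResponse
Gaimardia trapesina,species,TS6,2,Response
Gaimardia trapesina,species,TS7,2,NoResponse
Lasaea hinemoa,species,TS1,2,NoResponse
Lasaea hinemoa,species,TS2,2,NoResponse
Lasaea hinemoa,species,TS3,2,NoResponse
Lasaea hinemoa,species,TS4,2,NoResponse
Lasaea hinemoa,species,TS6,2,NoResponse
Lasaea hinemoa,species,TS7,2,NoResponse
Obrimoposthia ohlini,species,TS1,2,Response
Obrimoposthia ohlini,species,TS2,2,NoResponse
Obrimoposthia ohlini,species,TS3,2,NoResponse
Obrimoposthia ohlini,species,TS4,2,NoResponse
Obrimoposthia ohlini,species,TS6,2,NoResponse
Obrimoposthia ohlini,species,TS7,2,NoResponse
Obrimoposthia wandeli,species,TS1,1,NoResponse
Obrimoposthia wandeli,species,TS2,1,NoResponse
Obrimoposthia wandeli,species,TS3,1,NoResponse
Obrimoposthia wandeli,species,TS4,1,NoResponse
Obrimoposthia wandeli,species,TS5,1,NoResponse
Obrimoposthia wandeli,species,TS6,1,NoResponse
Obrimoposthia wandeli,species,TS7,1,NoResponse
Obrimoposthia wandeli,species,TS1,2,Response
Obrimoposthia wandeli,species,TS2,2,NoResponse
Obrimoposthia wandeli,species,TS3,2,NoResponse
Obrimoposthia wandeli,species,TS4,2,Response
Obrimoposthia wandeli,species,TS6,2,NoResponse
Obrimoposthia wandeli,species,TS7,2,NoResponse
Microtox,assay,TS1,1,NoResponse
Microtox,assay,TS2,1,NoResponse
Microtox,assay,TS3,1,NoResponse
Microtox,assay,TS4,1,Response
Microtox,assay,TS5,1,NoResponse
Microtox,assay,TS6,1,NoResponse
Microtox,assay,TS7,1,NoResponse
Microtox,assay,TS1,2,Response
Microtox,assay,TS2,2,Response
Microtox,assay,TS3,2,NoResponse
Microtox,assay,TS4,2,Response
Microtox,assay,TS6,2,NoResponse
Microtox,assay,TS7,2,NoResponse
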