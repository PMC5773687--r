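species,scenario,current_km2,loss_km2,stable_km2,gain_km2,net_pct
Jatropha curcas,RCP2.6,1269140,368,1268772,192280,15
Jatropha curcas,RCP8.5,1269140,276,1268864,278116,22
Aleurites moluccana,RCP2.6,340768,5704,335064,117392,33
Aleurites moluccana,RCP8.5,340768,3772,336996,175812,50
Ricinus communis,RCP2.6,1680620,73784,1606872,393024,19
Ricinus communis,RCP8.5,1680620,89240,1591416,561384,28
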