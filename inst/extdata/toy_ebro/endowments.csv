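district_id,tland_flood,tland_sprinkler,tland_drip,twater,tlabor,withdraw_reach,return_reach
alto_aragon,212.5,112.5,0,3340.75,1325,446,406
bardenas,75,100,0,1702,787.5,455,418
jalon,30,0,75,814.2,2775,463,421
lodosa,0,0,56.25,330.05,1875,433,264
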