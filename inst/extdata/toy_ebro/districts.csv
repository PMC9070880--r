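district_id,crop_id,group,tech,price,cost,water_req,labor_req,observed_acreage,avg_yield
alto_aragon,barley,field,flood,0.18,0.54,11,2,110,5.5
alto_aragon,corn,field,sprinkler,0.19,1.39,9.5,6,90,11
alto_aragon,alfalfa,field,flood,0.165,1.6275,14,5,60,13.5
bardenas,corn,field,sprinkler,0.19,1.39,9.5,6,80,11
bardenas,wheat,field,flood,0.19,0.678,12,2.5,60,6.2
jalon,fruit,fruit,drip,0.55,8.75,7,25,60,21
jalon,fruit,fruit,flood,0.55,8.25,12,30,24,19
lodosa,fruit,fruit,drip,0.55,8.75,7,25,20,21
lodosa,vegetables,vegetables,drip,0.35,5.792,5.88,40,25,30
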