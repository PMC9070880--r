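indicator,baseline,ic,eic,wm,ewm
water_use,5782,3632,3047,3627,3232
water_use_irrigation,5380,3230,2645,3225,2830
water_use_urban,402,402,402,402,402
exchanges,0,0,585,235,780
exchanges_between_irrigators,0,0,0,235,380
exchanges_with_environment,0,0,585,0,400
flow_at_mouth,8895,5350,5540,5345,5435
surface_area,529,332,275,348,293
surface_area_field,400,219,165,229,182
surface_area_fruit,104,93,90,97,90
surface_area_vegetables,25,20,20,22,21
private_benefits,2486,2321,2332,2340,2346
irrigation_benefits,629,464,475,483,489
irrigation_crop_benefits,629,464,NA,NA,393
irrigation_market_income,0,0,0,NA,42
irrigation_env_sale_income,0,0,NA,0,54
urban_benefits,1857,1857,1857,1857,1857
environmental_benefits,956,761,834,719,826
social_benefits,3442,3082,3105,3059,3118
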