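reach_id,downstream_id,length_km,local_inflow,min_env_flow,min_env_flow_drought,valuation_tier,beta,r_ir,r_urb,loss,flow_scale,closure
202,264,350,1700,0,0,high,-9.65,0.2,0.8,153.768493150685,0.00012714315008905,0
433,264,1300,1600,0,0,medium,-0.1,0.2,0.8,144.723287671233,0.0103055448389964,0
264,274,400,200,300,300,low,-2.07,0.2,0.8,18.0904109589041,0.000226726042130074,0
441,274,600,1200,0,0,high,-8.14,0.2,0.8,108.542465753425,0.000181151935882378,0
274,406,400,150,0,0,low,-1.42,0.2,0.8,13.5678082191781,0.000241189272281054,0
446,406,500,3600,0,0,high,-1.96,0.2,0.8,325.627397260274,0.00110295642612255,0
406,418,450,200,0,0,low,-16.39,0.2,0.8,18.0904109589041,1.46896972426926e-05,0
455,418,900,3400,0,0,high,-9.61,0.2,0.8,307.53698630137,8.94627630854384e-05,0
418,421,500,150,0,0,low,-1.89,0.2,0.8,13.5678082191781,9.18602033243213e-05,0
463,421,1300,1200,0,0,medium,-0.23,0.2,0.8,108.542465753425,0.0103893453419986,0
421,426,600,200,945,640,low,-0.12,0.2,0.8,18.0904109589041,0.00147370535730359,0
662,426,800,900,0,0,medium,-0.26,0.2,0.8,81.4068493150685,0.00565685729003263,0
426,428,580,80,0,0,low,-0.52,0.2,0.8,7.23616438356164,0.000302179448044519,0
428,NA,220,20,3000,3000,high,-0.3,0.2,0.8,1.80904109589041,0.000603124569021585,0
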