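compound_id,target_domain,k_lp,k_lp_sem,k_lpt,k_lpt_sem,alpha,auc,initial_rate,dc50,dc50_censored,dmax
12,BRD4-BD2,22,2,6,1,3.7,192,1.38,518,FALSE,91
13,BRD4-BD2,17,2,10,2,1.7,309,0.76,726,FALSE,78
14,BRD4-BD2,26,5,26.5,4,1,460,0.46,2260,FALSE,69
15,BRD4-BD2,31,4,39,5,0.8,733,0.21,10000,TRUE,NA
16,BRD4-BD2,33,5,49,6,0.7,900,0.08,10000,TRUE,NA
17,BRD4-BD2,20.5,3,1.5,0.5,13.7,39,1.95,40,FALSE,98
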