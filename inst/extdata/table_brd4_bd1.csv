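compound_id,target_domain,k_lp,k_lp_sem,k_lpt,k_lpt_sem,alpha,auc,initial_rate,dc50,dc50_censored,dmax
12,BRD4-BD1,22,2,31,4,0.7,192,1.38,518,FALSE,91
13,BRD4-BD1,17,2,29,3,0.6,309,0.76,726,FALSE,78
14,BRD4-BD1,26,5,33,4,0.8,460,0.46,2260,FALSE,69
15,BRD4-BD1,31,4,26.5,4,1.2,733,0.21,10000,TRUE,NA
16,BRD4-BD1,33,5,33,5,1,900,0.08,10000,TRUE,NA
17,BRD4-BD1,20.5,3,15,2,1.4,39,1.95,40,FALSE,98
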