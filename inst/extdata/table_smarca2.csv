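compound_id,target_domain,k_lp,k_lp_sem,k_lpt,k_lpt_sem,alpha,auc,initial_rate,dc50,dc50_censored,dmax
1,SMARCA2-BD,60,3,4.7,1,12.8,13,1.9,8,FALSE,98
2,SMARCA2-BD,210,18,33,4,6.5,28,2.02,95,FALSE,95
3,SMARCA2-BD,58,4,500,NA,0.1,NA,NA,10000,TRUE,NA
4,SMARCA2-BD,166,15,64,7,2.6,26,2.06,99,FALSE,96
5,SMARCA2-BD,84.7,5,46.8,6.7,1.8,28,1.9,112,FALSE,96
6,SMARCA2-BD,11,1,5.6,2,2,26,3.5,85,FALSE,96
7,SMARCA2-BD,9,2,80,6,0.11,122,0.78,850,FALSE,55
8,SMARCA2-BD,7,2,27,3,0.26,75,1.34,379,FALSE,80
9,SMARCA2-BD,25,4,77,8,0.32,85,0.98,372,FALSE,74
10,SMARCA2-BD,60,5,250,30,0.24,100,0.56,469,FALSE,65
11,SMARCA2-BD,59,5,108,14,0.55,119,0.25,221,FALSE,53
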