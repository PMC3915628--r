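comparison,positive,negative,n_pos,n_neg,auc,accuracy,features,sensitivity,specificity,ppv,npv,tolerance_pct,accuracy_digits
bd_hc,BD,HC,23,33,0.61,66.1,99,39.1,84.8,64.3,66.6,0.05,1
mdd_hc,MDD,HC,19,38,0.44,59.6,80,31.6,73.7,37.5,68.3,0.05,1
bd_mdd,MDD,BD,19,23,0.52,54.76,53,57.9,52.1,50.0,60.0,0.1,2
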