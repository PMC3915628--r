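row,description,a,b,c,d,printed_chi2
gender,males BD-I vs males MDD,9,14,4,15,1.59
handedness,right-handed BD-I vs MDD,23,0,16,3,3.91
antipsychotics,use at MRI BD-I vs MDD,10,13,15,4,5.43
mood_stabilizers,use at MRI BD-I vs MDD,12,11,4,15,4.27
antidepressants,use at MRI BD-I vs MDD,1,22,10,9,12.54
scanner_bd_hc,scanner 1 BD-I vs matched HC,13,10,24,9,1.59
scanner_mdd_hc,scanner 1 MDD vs matched HC,10,9,25,13,0.92
scanner_bd_mdd,scanner 1 BD-I vs MDD,13,10,10,9,0.064
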