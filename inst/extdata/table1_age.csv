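group,mean,sd,n
BD,27.09,8.87,23
MDD,29.05,8.34,19
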