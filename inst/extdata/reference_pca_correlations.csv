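a,b,r,significant
ALP,SOC,0.40,TRUE
ALP,TN,0.37,TRUE
ALP,MBC,0.59,TRUE
ALP,MBN,0.62,TRUE
NO3,CBH,-0.38,TRUE
NO3,ACP,NA,FALSE
NO3,BG,NA,FALSE
ACP,BG,NA,FALSE
POD,BX,NA,FALSE
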