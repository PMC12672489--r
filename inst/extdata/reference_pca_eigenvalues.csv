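component,eigenvalue,contribution_rate,cumulative_rate
PC1,6.366,31.828,31.828
PC2,2.196,10.980,42.808
PC3,1.948,9.739,52.547
PC4,1.759,8.795,61.341
PC5,1.368,6.839,68.181
PC6,1.101,5.504,73.684
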