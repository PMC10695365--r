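component,proportion
PC1,0.297
PC2,0.211
PC3,0.150
PC4,0.095
PC5,0.075
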