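study,treat_i,treat_j,cov
s012,B,C,0.0246
s013,B,D,0.1553
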