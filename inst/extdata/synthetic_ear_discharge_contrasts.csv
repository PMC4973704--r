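study,base,treat,y,v
s001,A,B,-1.8038,0.0201
s002,A,B,-1.0168,0.0224
s003,A,B,-0.7119,0.1081
s004,A,B,-0.8949,0.0992
s012,A,B,-2.1647,0.0492
s012,A,C,-1.3355,0.0492
s013,A,B,-2.0131,0.3106
s013,A,D,-1.8676,0.3106
s005,A,C,-0.8337,0.0333
s006,A,C,-0.6205,0.1786
s007,A,C,0.1711,0.1353
s008,A,D,0.4189,0.0407
s009,A,D,1.0806,0.1037
s010,B,C,0.9178,0.4995
s011,B,C,0.9199,0.1018
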