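element,etr,radius,charge
C,-0.105,2.0,0
H,-0.040,1.2,0
O,0.146,1.6,0
N,0.112,1.7,0
P,0.183,1.9,0
S,-0.108,1.85,0
NA,0.200,1.8,0
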