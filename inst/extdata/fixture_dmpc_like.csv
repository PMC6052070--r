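name,element,x,y,z,charge
NC,N,0,0,4.5,0.35
PO,P,0,0,2.7,-0.35
OG,O,0,0,0.9,
CA1,C,-1.5,0,-0.9,
CA2,C,-1.5,0,-2.7,
CA3,C,-1.5,0,-4.5,
CA4,C,-1.5,0,-6.3,
CA5,C,-1.5,0,-8.1,
CA6,C,-1.5,0,-9.9,
CB1,C,1.5,0,-0.9,
CB2,C,1.5,0,-2.7,
CB3,C,1.5,0,-4.5,
CB4,C,1.5,0,-6.3,
CB5,C,1.5,0,-8.1,
CB6,C,1.5,0,-9.9,
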