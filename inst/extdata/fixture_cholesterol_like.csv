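name,element,x,y,z
OH,O,0,0,1.8
C1,C,0,0,0
C2,C,0,0,-1.8
C3,C,0,0,-3.6
C4,C,0,0,-5.4
C5,C,0,0,-7.2
C6,C,0,0,-9.0
C7,C,0,0,-10.8
C8,C,0,0,-12.6
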