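name,element,x,y,z
OH,O,0,0,1.8
C1,C,0,0,0
C2,C,0,0,-1.8
C3,C,0,0,-3.6
C4,C,0,0,-5.4
C5,C,1.8,0,-5.4
C6,C,3.6,0,-5.4
C7,C,5.4,0,-5.4
C8,C,7.2,0,-5.4
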