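name,element,x,y,z
OS1,O,2.5000,0.0000,12.6
OS2,O,0.7725,2.3776,12.6
OS3,O,-2.0225,1.4695,12.6
OS4,O,-2.0225,-1.4695,12.6
OS5,O,0.7725,-2.3776,12.6
OS6,O,2.0225,1.4695,14.1
OS7,O,-0.7725,2.3776,14.1
OS8,O,-2.5000,0.0000,14.1
OS9,O,-0.7725,-2.3776,14.1
OS10,O,2.0225,-1.4695,14.1
CA1,C,0,0,9.6
CA2,C,0,0,7.8
CA3,C,0,0,6.0
CA4,C,0,0,4.2
CA5,C,0,0,2.4
CA6,C,0,0,0.6
CA7,C,0,0,-1.2
CA8,C,0,0,-3.0
CA9,C,0,0,-4.8
CA10,C,0,0,-6.6
CA11,C,0,0,-8.4
CA12,C,0,0,-10.2
CA13,C,0,0,-12.0
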