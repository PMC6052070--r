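name,element,x,y,z
C1,C,0.000,0.000,0.000
C2,C,1.250,0.550,0.193
C3,C,2.500,0.000,0.296
C4,C,3.750,0.550,0.259
C5,C,5.000,0.000,0.100
C6,C,6.250,0.550,-0.105
C7,C,7.500,0.000,-0.261
C8,C,8.750,0.550,-0.295
C9,C,10.000,0.000,-0.189
C10,C,11.250,0.550,0.005
C11,C,12.500,0.000,0.197
C12,C,13.750,0.550,0.296
C13,C,15.000,0.000,0.256
C14,C,16.250,0.550,0.096
C15,C,17.500,0.000,-0.110
C16,C,18.750,0.550,-0.264
C17,C,20.000,0.000,-0.294
C18,C,21.250,0.550,-0.185
C19,C,22.500,0.000,0.010
C20,C,23.750,0.550,0.201
C21,C,25.000,0.000,0.297
C22,C,26.250,0.550,0.254
C23,C,27.500,0.000,0.091
C24,C,28.750,0.550,-0.115
C25,C,30.000,0.000,-0.266
C26,C,31.250,0.550,-0.293
O1,O,-1.10,0.55,0.20
H1,H,0.000,1.000,0.400
H3,H,2.500,1.000,0.696
H5,H,5.000,1.000,0.500
H7,H,7.500,1.000,0.139
H9,H,10.000,1.000,0.211
H11,H,12.500,1.000,0.597
H13,H,15.000,1.000,0.656
H15,H,17.500,1.000,0.290
H17,H,20.000,1.000,0.106
H19,H,22.500,1.000,0.410
H21,H,25.000,1.000,0.697
H23,H,27.500,1.000,0.491
H25,H,30.000,1.000,0.134
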