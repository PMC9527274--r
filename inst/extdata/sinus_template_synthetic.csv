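lead,wave,q25,q50,q75
I,q,0,0,0.5
I,r,4,6,8
I,s,0,0,1.5
I,qrsd,84,92,100
II,q,0,0.5,1
II,r,8,10,13
II,s,0,1,2
II,qrsd,84,92,100
III,q,0,0.5,1.5
III,r,2,4,7
III,s,0,1,3
III,qrsd,84,92,100
aVR,q,0,0,0
aVR,r,0.5,1,2
aVR,s,4,6,9
aVR,qrsd,84,92,100
aVL,q,0,0,0.5
aVL,r,1,3,6
aVL,s,0,1,2
aVL,qrsd,84,92,100
aVF,q,0,0.5,1
aVF,r,4,7,10
aVF,s,0,1,2
aVF,qrsd,84,92,100
V1,q,0,0,0
V1,r,1,2,3.5
V1,s,6,9,12
V1,qrsd,84,92,100
V2,q,0,0,0
V2,r,3,5,8
V2,s,8,12,16
V2,qrsd,84,92,100
V3,q,0,0,0
V3,r,5,8,11
V3,s,4,7,10
V3,qrsd,84,92,100
V4,q,0,0,0
V4,r,10,14,18
V4,s,2,4,6
V4,qrsd,84,92,100
V5,q,0,0,0.5
V5,r,10,13,17
V5,s,1,2,4
V5,qrsd,84,92,100
V6,q,0,0,1
V6,r,8,11,14
V6,s,0,1,2
V6,qrsd,84,92,100
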