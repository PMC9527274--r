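group,lead,wave,q25,q50,q75
s-RVOT,I,q,0,0,0
s-RVOT,I,r,0.8,1.6,3.4
s-RVOT,I,s,0,0,1
s-RVOT,I,qrsd,100,112,120
s-RVOT,II,q,0,0,0
s-RVOT,II,r,14,17,19
s-RVOT,II,s,0,0,0
s-RVOT,II,qrsd,116,120,120
s-RVOT,III,q,0,0,0
s-RVOT,III,r,13,15.9,18.5
s-RVOT,III,s,0,0,0
s-RVOT,III,qrsd,112,120,120
s-RVOT,aVR,q,7.5,9.1,10.8
s-RVOT,aVR,r,0,0,0
s-RVOT,aVR,s,0,0,0
s-RVOT,aVR,qrsd,112,120,120
s-RVOT,aVL,q,5.9,7.4,9.2
s-RVOT,aVL,r,0,0,0
s-RVOT,aVL,s,0,0,0
s-RVOT,aVL,qrsd,96,108,120
s-RVOT,aVF,q,0,0,0
s-RVOT,aVF,r,13.5,16.1,18.5
s-RVOT,aVF,s,0,0,0
s-RVOT,aVF,qrsd,112,116,120
s-RVOT,V1,q,0,0,0
s-RVOT,V1,r,0.5,1.2,2.2
s-RVOT,V1,s,8,11.8,15.2
s-RVOT,V1,qrsd,104,120,124
s-RVOT,V2,q,0,0,0
s-RVOT,V2,r,2,3.3,5
s-RVOT,V2,s,13.8,19,24.2
s-RVOT,V2,qrsd,120,120,128
s-RVOT,V3,q,0,0,0
s-RVOT,V3,r,4.8,6.8,9.1
s-RVOT,V3,s,2.4,7.8,13
s-RVOT,V3,qrsd,120,120,128
s-RVOT,V4,q,0,0,0
s-RVOT,V4,r,8,10.2,13.7
s-RVOT,V4,s,0,0,0
s-RVOT,V4,qrsd,112,120,124
s-RVOT,V5,q,0,0,0
s-RVOT,V5,r,10.9,14,17
s-RVOT,V5,s,0,0,0
s-RVOT,V5,qrsd,112,120,124
s-RVOT,V6,q,0,0,0
s-RVOT,V6,r,12,14.5,17.1
s-RVOT,V6,s,0,0,0
s-RVOT,V6,qrsd,112,120,120
LVOT-ASC,I,q,0,0,0
LVOT-ASC,I,r,1.1,2.5,4.45
LVOT-ASC,I,s,0,0,1.38
LVOT-ASC,I,qrsd,97,112,120
LVOT-ASC,II,q,0,0,0
LVOT-ASC,II,r,15.85,20.05,23
LVOT-ASC,II,s,0,0,0
LVOT-ASC,II,qrsd,112,120,123
LVOT-ASC,III,q,0,0,0
LVOT-ASC,III,r,14.6,17.45,22.5
LVOT-ASC,III,s,0,0,0
LVOT-ASC,III,qrsd,112,120,124
LVOT-ASC,aVR,q,9.18,11,13
LVOT-ASC,aVR,r,0,0,0
LVOT-ASC,aVR,s,0,0,0
LVOT-ASC,aVR,qrsd,112,120,123
LVOT-ASC,aVL,q,0.63,8,11.38
LVOT-ASC,aVL,r,0,0,0.15
LVOT-ASC,aVL,s,0,0,0.6
LVOT-ASC,aVL,qrsd,100,114,120
LVOT-ASC,aVF,q,0,0,0
LVOT-ASC,aVF,r,15.73,19.3,22.7
LVOT-ASC,aVF,s,0,0,0
LVOT-ASC,aVF,qrsd,108,120,120
LVOT-ASC,V1,q,0,0,0
LVOT-ASC,V1,r,0.85,1.8,3.48
LVOT-ASC,V1,s,5.05,8.1,11.58
LVOT-ASC,V1,qrsd,100,112,123
LVOT-ASC,V2,q,0,0,0
LVOT-ASC,V2,r,4.73,6.95,10.08
LVOT-ASC,V2,s,10,14,19
LVOT-ASC,V2,qrsd,112,120,128
LVOT-ASC,V3,q,0,0,0
LVOT-ASC,V3,r,9.53,12.55,19.53
LVOT-ASC,V3,s,0,2.75,8.88
LVOT-ASC,V3,qrsd,112,120,128
LVOT-ASC,V4,q,0,0,0
LVOT-ASC,V4,r,12.98,18.5,25
LVOT-ASC,V4,s,0,0,0
LVOT-ASC,V4,qrsd,109,120,124
LVOT-ASC,V5,q,0,0,0
LVOT-ASC,V5,r,15.83,20.4,24.6
LVOT-ASC,V5,s,0,0,0
LVOT-ASC,V5,qrsd,109,120,120
LVOT-ASC,V6,q,0,0,0
LVOT-ASC,V6,r,14.85,16.85,21.75
LVOT-ASC,V6,s,0,0,0
LVOT-ASC,V6,qrsd,108,118,120
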