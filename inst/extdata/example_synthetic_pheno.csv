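subject_id,pedigree_id,visit,age,smoke,medicine,gender,SBP,DBP
s00001,ped001,1,48,0,0,1,120.1,77.9
s00001,ped001,2,50,0,0,1,117.5,78.9
s00002,ped001,1,20,0,0,2,114,76.9
s00002,ped001,2,22,0,0,2,118,77.1
s00002,ped001,3,24,0,0,2,114.4,77
s00002,ped001,4,26,0,0,2,110.8,79.5
s00003,ped001,1,24,0,0,1,122.4,76.8
s00003,ped001,2,26,1,0,1,121.9,78
s00004,ped001,1,30,0,0,1,115.9,78.3
s00004,ped001,2,32,1,0,1,117.4,76.8
s00004,ped001,3,34,0,0,1,115.2,76.4
s00005,ped002,1,26,1,0,2,113.7,75.4
s00005,ped002,2,28,1,1,2,120.5,77.8
s00005,ped002,3,30,1,1,2,118.3,77.1
s00006,ped002,1,41,0,1,1,113,76.5
s00006,ped002,2,43,0,0,1,113.9,77.1
s00006,ped002,3,45,0,0,1,117.1,76.3
s00006,ped002,4,47,0,0,1,113.7,76.2
s00007,ped002,1,41,0,1,1,119.1,81.1
s00007,ped002,2,43,0,0,1,118.7,77.2
s00007,ped002,3,45,0,0,1,121.5,77.1
s00007,ped002,4,47,0,0,1,116,80.6
s00008,ped002,1,21,0,1,1,107.7,66
s00008,ped002,2,23,0,0,1,108.2,69.8
s00009,ped003,1,31,0,1,2,114.6,79.5
s00009,ped003,2,33,1,1,2,124.9,82.4
s00010,ped003,1,40,0,0,2,107.4,65.9
s00010,ped003,2,42,0,0,2,110,64.1
s00010,ped003,3,44,1,0,2,104.8,68.3
s00011,ped003,1,24,1,0,2,122.1,78.5
s00011,ped003,2,26,0,0,2,123.5,80.1
s00011,ped003,3,28,0,0,2,116.8,81.3
s00011,ped003,4,30,0,1,2,117.4,77.2
s00012,ped003,1,69,0,0,2,106.3,71.2
s00012,ped003,2,71,1,0,2,112.9,72.6
s00012,ped003,3,73,1,1,2,109.9,73.6
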