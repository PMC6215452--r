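"V1","V2","V3","V4","V5"
4,4,3,4,4
6,4,5,5,6
5,5,5,4,5
5,5,6,6,6
5,4,4,4,5
7,6,5,NA,NA
2,2,3,2,3
3,4,4,NA,4
4,4,5,NA,5
6,6,6,6,6
NA,0,0,0,1
5,4,5,NA,4
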