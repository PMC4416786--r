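molecule,group,status,level,sem,loq
hMDR1,C57BL6_WT,ULQ,,,0.112
hMDR1,HMDR1,expressed,0.355,0.068,
Mdr1a,C57BL6_WT,expressed,22.3,2.9,
Mdr1a,HMDR1,expressed,2.45,0.19,
MDR1_Mdr1a,C57BL6_WT,expressed,25.3,1.5,
MDR1_Mdr1a,HMDR1,expressed,2.60,0.33,
Mdr1b,C57BL6_WT,ULQ,,,0.136
Mdr1b,HMDR1,ULQ,,,0.134
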