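strain,sra,control,genotype_mismatch,method,replicate,value
BY4741,NA,TRUE,FALSE,chef,1,165
BY4741,NA,TRUE,FALSE,chef,2,160
BY4741,NA,TRUE,FALSE,chef,3,163
BY4741,NA,TRUE,FALSE,wgs_reseq,1,141
BY4741,NA,TRUE,FALSE,ddpcr,1,126
BY4741,NA,TRUE,FALSE,ddpcr,2,135
BY4741,NA,TRUE,FALSE,ddpcr,3,129
B30,NA,TRUE,FALSE,wgs_reseq,1,30
B30,NA,TRUE,FALSE,ddpcr,1,25
B30,NA,TRUE,FALSE,ddpcr,2,26
B30,NA,TRUE,FALSE,ddpcr,3,25
AHR,ERR1308770,FALSE,FALSE,wgs_sra,1,31
AHR,ERR1308770,FALSE,FALSE,chef,1,166
AHR,ERR1308770,FALSE,FALSE,chef,2,174
AHR,ERR1308770,FALSE,FALSE,chef,3,171
AHR,ERR1308770,FALSE,FALSE,wgs_reseq,1,157
AFG,ERR1309145,FALSE,TRUE,wgs_sra,1,50
AFG,ERR1309145,FALSE,TRUE,chef,1,124
AFG,ERR1309145,FALSE,TRUE,chef,2,129
AFG,ERR1309145,FALSE,TRUE,chef,3,127
AFG,ERR1309145,FALSE,TRUE,wgs_reseq,1,111
AFG,ERR1309145,FALSE,TRUE,ddpcr,1,113
AFG,ERR1309145,FALSE,TRUE,ddpcr,2,107
AFG,ERR1309145,FALSE,TRUE,ddpcr,3,107
ACQ,ERR1308618,FALSE,TRUE,wgs_sra,1,74
ACQ,ERR1308618,FALSE,TRUE,chef,1,114
ACQ,ERR1308618,FALSE,TRUE,wgs_reseq,1,96
AHG,ERR1308781,FALSE,FALSE,wgs_sra,1,69
AHG,ERR1308781,FALSE,FALSE,chef,1,91
AHG,ERR1308781,FALSE,FALSE,wgs_reseq,1,93
AHG,ERR1308781,FALSE,FALSE,ddpcr,1,75
AHG,ERR1308781,FALSE,FALSE,ddpcr,2,78
AHG,ERR1308781,FALSE,FALSE,ddpcr,3,81
AEF,ERR1308873,FALSE,FALSE,wgs_sra,1,79
AEF,ERR1308873,FALSE,FALSE,chef,1,177
AEF,ERR1308873,FALSE,FALSE,wgs_reseq,1,146
ACV,ERR1308596,FALSE,FALSE,wgs_sra,1,92
ACV,ERR1308596,FALSE,FALSE,chef,1,96
AHQ,ERR1309019,FALSE,FALSE,wgs_sra,1,93
AHQ,ERR1309019,FALSE,FALSE,chef,1,145
AHQ,ERR1309019,FALSE,FALSE,chef,2,151
AHQ,ERR1309019,FALSE,FALSE,chef,3,149
AHQ,ERR1309019,FALSE,FALSE,wgs_reseq,1,105
AHQ,ERR1309019,FALSE,FALSE,ddpcr,1,90
AHQ,ERR1309019,FALSE,FALSE,ddpcr,2,98
AHQ,ERR1309019,FALSE,FALSE,ddpcr,3,87
CEB,ERR1309017,FALSE,FALSE,wgs_sra,1,109
CEB,ERR1309017,FALSE,FALSE,chef,1,133
CEB,ERR1309017,FALSE,FALSE,wgs_reseq,1,82
ACK,ERR1308893,FALSE,FALSE,wgs_sra,1,116
ACK,ERR1308893,FALSE,FALSE,chef,1,124
ACK,ERR1308893,FALSE,FALSE,wgs_reseq,1,97
ADA,ERR1309427,FALSE,FALSE,wgs_sra,1,121
ADA,ERR1309427,FALSE,FALSE,chef,1,133
ADA,ERR1309427,FALSE,FALSE,wgs_reseq,1,116
AAA,ERR1309487,FALSE,FALSE,wgs_sra,1,136
AAA,ERR1309487,FALSE,FALSE,chef,1,171
AAA,ERR1309487,FALSE,FALSE,chef,2,169
AAA,ERR1309487,FALSE,FALSE,chef,3,171
AAA,ERR1309487,FALSE,FALSE,wgs_reseq,1,139
AAA,ERR1309487,FALSE,FALSE,ddpcr,1,135
AAA,ERR1309487,FALSE,FALSE,ddpcr,2,133
AAA,ERR1309487,FALSE,FALSE,ddpcr,3,137
ABS,ERR1309033,FALSE,FALSE,wgs_sra,1,201
ABS,ERR1309033,FALSE,FALSE,chef,1,210
ABS,ERR1309033,FALSE,FALSE,chef,2,226
ABS,ERR1309033,FALSE,FALSE,chef,3,221
ABS,ERR1309033,FALSE,FALSE,wgs_reseq,1,179
ABS,ERR1309033,FALSE,FALSE,ddpcr,1,195
ABS,ERR1309033,FALSE,FALSE,ddpcr,2,192
ABS,ERR1309033,FALSE,FALSE,ddpcr,3,180
AEQ,ERR1309512,FALSE,FALSE,wgs_sra,1,218
AEQ,ERR1309512,FALSE,FALSE,chef,1,254
AEQ,ERR1309512,FALSE,FALSE,chef,2,287
AEQ,ERR1309512,FALSE,FALSE,chef,3,265
AEQ,ERR1309512,FALSE,FALSE,wgs_reseq,1,218
CEV,ERR1308745,FALSE,FALSE,wgs_sra,1,243
CEV,ERR1308745,FALSE,FALSE,chef,1,306
CEV,ERR1308745,FALSE,FALSE,chef,2,306
CEV,ERR1308745,FALSE,FALSE,chef,3,300
CEV,ERR1308745,FALSE,FALSE,wgs_reseq,1,255
CEV,ERR1308745,FALSE,FALSE,ddpcr,1,238
CEV,ERR1308745,FALSE,FALSE,ddpcr,2,216
CEV,ERR1308745,FALSE,FALSE,ddpcr,3,228
AES,ERR1309368,FALSE,FALSE,wgs_sra,1,259
AES,ERR1309368,FALSE,FALSE,chef,1,226
AGC,ERR1309000,FALSE,TRUE,wgs_sra,1,275
AGC,ERR1309000,FALSE,TRUE,chef,1,145
AGC,ERR1309000,FALSE,TRUE,wgs_reseq,1,114
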