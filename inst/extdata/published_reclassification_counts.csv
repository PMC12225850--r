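alternative,block,n,cc,ci,ic,ii
LDL-C_M-180,<70,964,635,65,186,78
LDL-C_M-180,70-99,3793,2861,188,359,385
LDL-C_M-180,100-129,4158,3186,185,268,519
LDL-C_M-180,130-159,2168,1664,64,99,341
LDL-C_M-180,160-189,677,507,14,21,135
LDL-C_M-180,>=190,170,130,1,9,30
LDL-C_M-180,overall,11930,8983,517,942,1488
LDL-C_KO-28,<70,964,643,57,189,75
LDL-C_KO-28,70-99,3793,2886,163,378,366
LDL-C_KO-28,100-129,4158,3235,136,243,544
LDL-C_KO-28,130-159,2168,1648,80,139,301
LDL-C_KO-28,160-189,677,481,40,48,108
LDL-C_KO-28,>=190,170,120,11,10,29
LDL-C_KO-28,overall,11930,9013,487,1007,1423
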