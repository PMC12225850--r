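method,cn_lt50,cn_50_99,cn_100_149,cn_150_199,cn_200_299,cn_300_399,cn_overall,n_overall
LDL-C_F,940,3934,2550,1159,734,183,9500,11930
LDL-C_M-10,958,3941,2623,1222,854,276,9874,11930
LDL-C_M-180,978,3957,2635,1225,866,264,9925,11930
LDL-C_KM-6-TG,979,3934,2617,1224,870,274,9898,11930
LDL-C_KO-6-TG,981,3948,2627,1224,870,274,9924,11930
LDL-C_KM-10,959,3924,2630,1227,865,270,9875,11930
LDL-C_KO-10,948,3963,2638,1235,866,277,9927,11930
LDL-C_KM-12-TG,985,3948,2617,1224,870,274,9918,11930
LDL-C_KO-12-TG,992,3954,2632,1231,868,277,9954,11930
LDL-C_KM-12,983,3950,2627,1227,856,274,9927,11930
LDL-C_KO-12,990,3963,2638,1235,873,278,9977,11930
LDL-C_KM-28,972,3944,2635,1242,873,284,9950,11930
LDL-C_KO-28,992,3967,2652,1247,876,286,10020,11930
LDL-C_KM-180,972,3968,2649,1242,873,282,9986,11930
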