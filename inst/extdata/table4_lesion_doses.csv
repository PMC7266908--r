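patient_id,lesion_id,location,mono_olinda_gy_per_gbq,mono_planet_gy_per_gbq,bi_olinda_gy_per_gbq,bi_planet_gy_per_gbq,data_flag
2,1,liver,4.94,3.29,NA,NA,not_reliable
2,2,liver,2.10,2.20,NA,NA,
2,3,liver,2.85,4.85,NA,NA,
2,4,other,5.85,5.72,NA,NA,
3,1,liver,5.05,5.02,5.05,3.09,
3,2,liver,1.63,1.54,1.92,1.56,
3,3,other,1.15,1.36,1.64,1.43,
4,1,liver,7.02,7.66,3.78,3.75,
4,2,liver,3.78,3.26,7.02,5.85,
5,1,liver,12.26,14.40,12.25,9.93,
5,2,liver,6.35,8.87,6.35,4.79,
5,3,other,3.89,3.71,3.89,3.85,
5,4,other,2.42,2.72,4.38,2.65,
6,1,other,1.71,1.31,3.05,1.33,
7,1,liver,5.10,5.57,5.10,4.92,
7,2,liver,5.13,6.05,5.13,4.85,
7,3,liver,7.29,7.45,7.29,8.09,
7,4,liver,3.94,5.48,3.94,4.40,
7,5,other,0.99,1.16,1.40,1.16,
8,1,liver,3.78,3.77,3.78,3.29,
8,2,liver,2.38,2.23,2.62,1.94,
8,3,liver,2.93,3.92,2.93,4.20,
8,4,liver,0.99,1.36,1.09,1.40,
8,5,liver,0.86,1.36,0.86,0.68,
8,6,other,3.00,3.28,3.18,3.20,
9,1,liver,0.87,1.09,0.87,1.07,
9,2,other,3.00,3.27,1.86,2.39,
10,1,liver,1.31,1.38,1.31,1.55,
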