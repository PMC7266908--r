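patient_id,target,model,olinda_gy_per_gbq,planet_gy_per_gbq,data_flag
1,kidneys,mono,0.61,0.62,
2,kidneys,mono,0.37,0.29,single_kidney
3,kidneys,mono,0.31,0.43,
4,kidneys,mono,0.24,0.33,
5,kidneys,mono,0.22,0.16,
6,kidneys,mono,1.30,0.74,
7,kidneys,mono,0.44,0.49,
8,kidneys,mono,0.38,0.52,
9,kidneys,mono,0.62,0.61,
10,kidneys,mono,0.44,0.50,
1,red_marrow,mono,0.063,0.015,
2,red_marrow,mono,0.088,0.005,
3,red_marrow,mono,0.067,0.022,
4,red_marrow,mono,0.048,0.015,
5,red_marrow,mono,0.063,0.012,
6,red_marrow,mono,0.060,0.017,
7,red_marrow,mono,0.081,0.015,
8,red_marrow,mono,0.058,0.015,
9,red_marrow,mono,0.064,0.017,
10,red_marrow,mono,0.040,0.030,
1,kidneys,bi,0.61,0.62,
2,kidneys,bi,0.37,0.30,single_kidney
3,kidneys,bi,0.44,0.44,
4,kidneys,bi,0.32,0.27,
5,kidneys,bi,0.22,0.19,
6,kidneys,bi,0.30,0.74,
7,kidneys,bi,0.56,0.52,
8,kidneys,bi,0.40,0.58,
9,kidneys,bi,0.62,0.66,
10,kidneys,bi,0.55,0.50,
1,red_marrow,bi,0.095,0.008,
2,red_marrow,bi,0.098,0.004,
3,red_marrow,bi,0.115,0.007,
4,red_marrow,bi,0.094,0.007,
5,red_marrow,bi,0.010,0.007,suspected_typo
6,red_marrow,bi,0.095,0.009,
7,red_marrow,bi,0.117,0.008,
8,red_marrow,bi,0.094,0.007,
9,red_marrow,bi,0.068,0.008,
10,red_marrow,bi,0.082,0.015,
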