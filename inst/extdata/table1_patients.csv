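patient_id,age_y,sex,primary_tumour,grade,administered_mbq,liver_lesions,other_lesions
1,69,M,Lung,2,7131,0,0
2,74,M,Pancreas,1,7253,3,1
3,57,F,Ileum,1,7176,2,1
4,45,M,Ileum,2,7271,2,0
5,74,M,Unknown,1,7188,2,2
6,63,F,MTC,NA,7212,0,1
7,76,F,Ileum,2,7613,4,1
8,68,M,Pancreas,1,7476,5,1
9,73,F,Unknown,1,7338,1,1
10,71,F,Ileum,1,7373,2,0
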