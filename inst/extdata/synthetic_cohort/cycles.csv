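"patient_id","afc","gn_start_iu","gn_total_iu","stim_days","e2_hcg","oocytes","fert_2pn","polypronucleate","cleaved","available_embryos","transferred","implanted","clinical_pregnancy","cumulative_pregnancy"
1,12,150,1598,12,5012.5,6,4,0,4,4,2,1,1,1
2,14,150,1530,9,3937,7,4,1,4,4,2,1,1,1
3,5,300,2359,8,944.9,4,2,0,2,1,1,0,0,0
4,3,300,3063,11,2465.9,4,2,0,2,1,1,0,0,0
5,6,300,3252,12,2781.3,9,7,0,5,5,3,1,1,1
6,5,300,3189,11,2357.2,2,2,0,2,2,2,1,1,1
7,8,225,2310,12,1179.4,9,6,0,2,2,2,1,1,1
8,8,225,2477,11,2536.9,7,6,0,5,3,2,0,0,0
9,5,300,2806,11,1275.4,7,4,1,4,3,2,2,1,1
10,14,150,1605,10,1087.3,9,3,1,3,3,2,1,1,1
11,14,150,1869,12,2757.5,10,9,0,8,7,2,2,1,1
12,5,300,4011,12,3252.9,3,2,0,2,2,2,0,0,0
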