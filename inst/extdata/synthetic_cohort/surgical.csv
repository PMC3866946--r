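"patient_id","record_type","site","side","depth_or_kind","size_or_enclosure","fimbria_enclosed"
1,"lesion","peritoneum","","superficial","1.69",""
1,"lesion","peritoneum","","deep","1.97",""
1,"lesion","ovary_left","","deep","2.37",""
1,"culdesac","","","","complete",""
2,"lesion","peritoneum","","superficial","2.24",""
2,"lesion","peritoneum","","deep","1.39",""
2,"lesion","ovary_left","","superficial","1.84",""
2,"lesion","ovary_right","","superficial","0.73",""
2,"adhesion","ovary","left","filmy","one_to_two_thirds","FALSE"
2,"adhesion","ovary","right","dense","lt_one_third","FALSE"
2,"culdesac","","","","none",""
3,"lesion","peritoneum","","superficial","0.16",""
3,"lesion","peritoneum","","deep","1.79",""
3,"lesion","ovary_left","","deep","4.69",""
3,"lesion","ovary_right","","superficial","0.31",""
3,"adhesion","ovary","left","dense","one_to_two_thirds","FALSE"
3,"adhesion","tube","left","filmy","one_to_two_thirds","FALSE"
3,"adhesion","tube","right","dense","lt_one_third","FALSE"
3,"culdesac","","","","none",""
4,"lesion","peritoneum","","superficial","5.08",""
4,"lesion","ovary_right","","superficial","0.82",""
4,"culdesac","","","","none",""
5,"lesion","peritoneum","","superficial","0.95",""
5,"lesion","ovary_left","","deep","4.04",""
5,"adhesion","ovary","left","filmy","one_to_two_thirds","FALSE"
5,"adhesion","ovary","right","filmy","gt_two_thirds","FALSE"
5,"culdesac","","","","partial",""
6,"lesion","peritoneum","","superficial","4.12",""
6,"adhesion","ovary","left","filmy","lt_one_third","FALSE"
6,"adhesion","tube","left","filmy","lt_one_third","FALSE"
6,"adhesion","tube","right","dense","lt_one_third","FALSE"
6,"culdesac","","","","none",""
7,"lesion","ovary_right","","deep","2.28",""
7,"adhesion","ovary","left","dense","one_to_two_thirds","FALSE"
7,"culdesac","","","","none",""
8,"lesion","peritoneum","","superficial","1.25",""
8,"lesion","ovary_left","","superficial","0.42",""
8,"lesion","ovary_left","","deep","5.12",""
8,"lesion","ovary_right","","superficial","0.42",""
8,"lesion","ovary_right","","deep","4.07",""
8,"adhesion","ovary","right","filmy","one_to_two_thirds","FALSE"
8,"adhesion","tube","right","filmy","lt_one_third","FALSE"
8,"culdesac","","","","none",""
9,"lesion","peritoneum","","superficial","0.92",""
9,"adhesion","tube","left","filmy","lt_one_third","FALSE"
9,"culdesac","","","","partial",""
10,"lesion","peritoneum","","superficial","1.17",""
10,"adhesion","ovary","left","filmy","one_to_two_thirds","FALSE"
10,"adhesion","tube","right","dense","lt_one_third","TRUE"
10,"culdesac","","","","none",""
11,"lesion","peritoneum","","superficial","1.01",""
11,"lesion","peritoneum","","deep","2.53",""
11,"lesion","ovary_left","","deep","3.71",""
11,"adhesion","ovary","left","filmy","one_to_two_thirds","FALSE"
11,"culdesac","","","","partial",""
12,"lesion","peritoneum","","superficial","1.84",""
12,"lesion","ovary_right","","superficial","0.8",""
12,"adhesion","ovary","left","dense","one_to_two_thirds","FALSE"
12,"adhesion","ovary","right","filmy","one_to_two_thirds","FALSE"
12,"culdesac","","","","partial",""
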