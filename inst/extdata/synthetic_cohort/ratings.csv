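"patient_id","side","tube","fimbria","ovary","ovary_present"
1,"left",4,4,4,TRUE
1,"right",4,4,4,TRUE
2,"left",3,4,3,TRUE
2,"right",4,3,3,TRUE
3,"left",3,3,2,TRUE
3,"right",3,3,3,TRUE
4,"left",4,4,0,FALSE
4,"right",4,4,3,TRUE
5,"left",4,4,3,TRUE
5,"right",4,3,2,TRUE
6,"left",2,3,3,TRUE
6,"right",3,3,4,TRUE
7,"left",4,4,2,TRUE
7,"right",4,4,3,TRUE
8,"left",4,4,3,TRUE
8,"right",2,3,3,TRUE
9,"left",3,3,4,TRUE
9,"right",3,4,4,TRUE
10,"left",4,4,3,TRUE
10,"right",3,1,4,TRUE
11,"left",4,4,3,TRUE
11,"right",4,4,4,TRUE
12,"left",4,4,2,TRUE
12,"right",4,4,3,TRUE
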