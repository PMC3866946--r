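"patient_id","age_years","infertility_years","prior_pregnancy","bmi","basal_fsh","basal_lh","basal_e2"
1,31.4,7.4,0,21.8,9,10.6,17.7
2,33.1,3.2,0,16.5,6,4.4,18.4
3,40.8,5.3,0,19.1,9.3,6.9,145.9
4,40.6,4.8,1,19.7,11.3,2.9,63.3
5,37,9.2,1,21.4,7.4,3.7,35.1
6,27.9,3.3,0,22.6,6.1,2.8,22.9
7,32.5,2.8,1,17.8,9.6,3.6,56.3
8,31,2.9,0,19.4,7.5,2.1,49.7
9,27.3,2.1,1,21.1,10,3.9,31.3
10,33.7,3.7,0,22.1,5.1,2.9,13.6
11,30,2.3,0,17.9,7.3,4.6,23.3
12,33.2,6.2,0,22.2,7.9,2.7,88.5
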