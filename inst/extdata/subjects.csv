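subject_id,age_years,sex,height_cm,bmi,jvp_mmhg,cf_supine_n,cf_tilt16_n,cf_valsalva_n
1,31,M,173,25.1,3.1,7.4,3.6,14.3
2,32,M,168,26.6,2.0,5.0,NA,24.7
3,28,M,183,23.7,3.2,8.0,4.1,NA
4,30,M,170,21.5,2.1,4.3,3.2,NA
5,64,M,180,23.7,4.0,8.5,4.7,17.0
6,26,M,180,20.9,3.6,8.1,5.4,19.4
7,28,M,175,28.1,2.5,7.2,4.2,11.7
8,30,M,175,23.8,1.7,3.5,2.2,12.3
9,72,M,173,25.8,4.5,9.8,NA,NA
10,26,M,178,23.0,2.3,6.1,4.3,14.6
11,29,M,191,30.0,3.3,7.6,5.1,NA
12,30,M,173,25.8,3.1,7.2,4.0,11.6
13,24,M,165,25.8,2.8,6.3,3.7,12.2
14,30,M,173,25.1,4.3,9.8,NA,29.9
15,30,F,163,24.0,3.0,7.3,4.1,20.4
16,27,F,163,20.6,3.1,7.0,3.9,10.3
17,25,F,173,17.5,1.3,3.5,2.1,10.6
18,26,M,180,24.4,2.1,6.2,2.4,13.8
19,30,F,165,21.1,3.8,8.9,NA,NA
20,28,M,170,23.5,4.5,10.5,5.7,19.5
21,28,F,150,21.2,3.2,8.5,2.5,15.8
22,31,F,160,24.3,2.4,5.7,2.6,NA
23,30,M,178,22.2,2.3,5.8,NA,11.5
24,25,F,157,20.1,3.0,NA,3.0,13.9
25,26,M,173,18.2,2.3,4.5,3.8,10.7
26,31,M,175,22.0,2.9,5.6,2.2,21.4
27,29,F,165,21.1,3.3,8.7,4.4,21.8
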