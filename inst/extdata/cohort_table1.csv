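subject_id,age,egfr,acr,gender,group,cohort
52815,39,169.45,0.68,F,control,1
21206,39,94.85,1.11,F,control,1
52855,46,131.85,0.85,F,control,1
52805,47,145.27,0.47,F,control,1
21227,20,134.71,0.81,F,control,1
21246,24,74.53,0.51,F,control,1
21216,25,113.26,0.19,F,control,1
52778,70,134.61,0.3,F,control,1
52757,51,150.26,0.32,F,control,1
21225,50,119.12,0.35,F,control,1
52803,11,70.77,0.4,M,control,1
52833,26,153.98,1.6,M,control,1
52856,46,92.64,0.95,M,control,1
52839,47,120.56,1.06,M,control,1
52839,47,85.62,1.06,M,control,1
52777,57,160.36,1.03,M,control,1
52823,57,136.93,0.48,M,control,1
52818,66,145.09,0.67,M,control,1
21241,67,83.58,0.36,M,control,1
52861,68,102.38,1.71,M,control,1
52866,69,3,107.25,F,ckd,1
21245,28,29,8.27,F,ckd,1
52838,65,49,1.67,F,ckd,1
52973,49,51,30.68,F,ckd,1
52845,38,75,13.79,F,ckd,1
21240,39,92,119.93,F,ckd,1
52854,25,93,3.76,F,ckd,1
21244,35,99,11.23,F,ckd,1
52827,46,114,141.83,F,ckd,1
52871,60,123,82.99,F,ckd,1
52852,24,84.05,123.34,M,ckd,1
52840,41,123.38,10.61,M,ckd,1
52829,28,153.97,1925.38,M,ckd,1
52830,25,181.34,17.89,M,ckd,1
52842,48,11.04,2.69,M,ckd,1
52875,47,30.99,0.91,M,ckd,1
52842,48,11.04,2.69,M,ckd,1
52828,60,22.58,87.79,M,ckd,1
52862,60,54.94,3.05,M,ckd,1
52832,65,4.95,0.54,M,ckd,1
52768,33,185.43,1.32,F,control,2
52811,4,85.97,0.71,F,control,2
21213,14,92.56,0.52,F,control,2
21214,16,75.12,0.37,F,control,2
52812,16,68.11,2.51,F,control,2
21231,18,78.64,0.86,F,control,2
21229,20,129.93,0.76,F,control,2
21218,27,140.59,1.92,F,control,2
52825,62,153.39,1.84,F,control,2
21217,21,91.94,0.78,F,control,2
21210,17,72.7,0.26,M,control,2
21223,18,83.16,2.02,M,control,2
21232,21,165.3,1.24,M,control,2
21212,24,153.06,0.26,M,control,2
52804,33,217.41,1.21,M,control,2
21235,37,151.17,0.88,M,control,2
21243,48,123.11,1.14,M,control,2
52728,49,68.92,0.52,M,control,2
52759,59,85.61,0.89,M,control,2
52772,63,87.59,1.36,M,control,2
52865,65,1,0.68,F,ckd,2
52877,22,3,0.62,F,ckd,2
52834,71,11,0.91,F,ckd,2
21237,7,14,0.68,F,ckd,2
52859,30,17,1.04,F,ckd,2
21238,50,26,0.6,F,ckd,2
52867,71,35,0.53,F,ckd,2
21249,62,41,2.78,F,ckd,2
52857,28,46,46.4,F,ckd,2
52858,35,17,7.2,F,ckd,2
52843,22,157.26,2.55,M,ckd,2
52844,24,19.68,0.97,M,ckd,2
52864,28,5.37,5.03,M,ckd,2
52831,33,194.92,10,M,ckd,2
52873,35,24.3,1.2,M,ckd,2
52870,37,13.96,1.08,M,ckd,2
21248,39,5.92,2.08,M,ckd,2
52879,39,8.5,0.57,M,ckd,2
52835,44,5.15,4.33,M,ckd,2
52869,59,3.07,0.51,M,ckd,2
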