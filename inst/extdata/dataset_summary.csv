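dataset,mouse_id,sex,n_planes,n_on,n_off,n_dual,n_simple,n_complex,layers_correlation,layers_significant
1,P02,F,4,479,346,144,82,62,0.12,TRUE
2,P02,F,7,821,936,415,248,167,-0.01,FALSE
3,P03,F,6,274,294,47,33,14,0.29,TRUE
4,P03,F,5,483,706,350,159,191,0.27,TRUE
5,P04,M,8,319,549,95,64,31,0.15,TRUE
6,P04,M,8,447,600,232,136,96,0.03,TRUE
7,P03,F,6,379,895,307,131,176,0.31,TRUE
8,P05,F,7,692,3037,1071,376,695,0.43,TRUE
9,P05,F,8,383,1992,293,146,147,0.28,TRUE
10,P06,M,7,317,1178,272,124,148,0.63,TRUE
11,P06,M,8,310,524,62,27,35,0.55,TRUE
12,P07,F,6,974,1263,419,163,256,0.41,TRUE
13,P07,F,6,662,1052,723,316,407,0.17,TRUE
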