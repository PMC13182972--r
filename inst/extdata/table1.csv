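variant,measurement,value,sem,n
WT,homo_cse,100,NA,4
WT,homo_e4031_cse,186.8,9.6,4
L615F,homo_cse,6.4,1.1,4
L615F,homo_e4031_cse,14.6,1.3,4
L615F,total_coexpr_cse,46.9,2.2,4
L615F,wt_residual_cse,41.0,4.2,4
L615F,wt_rescue_cse,35.3,4.2,4
L615F,mave_cse,0,NA,1
N470D,homo_cse,2.2,0.6,4
N470D,homo_e4031_cse,38.2,3.4,4
N470D,total_coexpr_cse,41.0,3.6,4
N470D,wt_residual_cse,33.9,4.3,4
N470D,wt_rescue_cse,18.3,2.8,4
I400N,homo_cse,3.9,0.5,4
I400N,homo_e4031_cse,61.5,5.1,4
I400N,total_coexpr_cse,51.8,1.9,4
I400N,wt_residual_cse,38.8,3.5,4
I400N,wt_rescue_cse,31.7,4.4,4
I400N,mave_cse,0,NA,1
H402R,homo_cse,12.9,1.3,4
H402R,homo_e4031_cse,85.2,5.2,4
H402R,total_coexpr_cse,62.8,6.4,4
H402R,wt_residual_cse,47.0,6.4,4
H402R,wt_rescue_cse,43.3,5.9,4
H402R,mave_cse,0,NA,1
R472P,homo_cse,3.4,1.0,4
R472P,homo_e4031_cse,15.2,0.7,4
R472P,total_coexpr_cse,50.6,7.5,4
R472P,wt_residual_cse,47.9,2.0,4
R472P,wt_rescue_cse,19.5,2.8,4
T473P,homo_cse,6.1,1.4,4
T473P,homo_e4031_cse,6.7,1.3,4
T473P,total_coexpr_cse,48.2,2.0,4
T473P,wt_residual_cse,34.1,5.8,4
T473P,wt_rescue_cse,6.0,1.4,4
T473P,mave_cse,0,NA,1
T474I,homo_cse,8.3,1.4,4
T474I,homo_e4031_cse,74.8,3.3,4
T474I,total_coexpr_cse,57.2,4.4,4
T474I,wt_residual_cse,54.9,5.0,4
T474I,wt_rescue_cse,39.9,5.3,4
Y475C,homo_cse,13.1,1.9,4
Y475C,homo_e4031_cse,43.0,2.4,4
Y475C,total_coexpr_cse,59.2,4.9,4
Y475C,wt_residual_cse,46.6,5.8,4
Y475C,wt_rescue_cse,42.8,6.0,4
V483F,homo_cse,5.4,1.4,4
V483F,homo_e4031_cse,46.8,4.8,4
V483F,total_coexpr_cse,68.8,5.7,4
V483F,wt_residual_cse,63.1,9.2,4
V483F,wt_rescue_cse,42.7,4.2,4
V483F,mave_cse,0,NA,1
H492L,homo_cse,17.5,3.4,4
H492L,homo_e4031_cse,103.1,11.3,4
H492L,total_coexpr_cse,56.5,6.8,4
H492L,wt_residual_cse,48.1,3.9,4
H492L,wt_rescue_cse,51.9,7.6,4
H492L,mave_cse,0,NA,1
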