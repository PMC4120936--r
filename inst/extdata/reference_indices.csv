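species,salience_n_part,salience_n_cit,composite_s,ci_n_part,ci_n_cit,ci_n_cat,ci
BD,40,33,0.53,40,193,8,4.83
BeC,40,0,0.00,40,122,9,3.05
BuC,40,4,0.03,40,68,6,1.70
CB,40,1,0.02,40,88,5,2.20
EG,40,38,0.71,38,161,9,4.24
GP,40,1,0.01,36,67,6,1.86
KS,40,6,0.05,32,98,7,3.06
LG,40,18,0.21,40,145,8,3.63
MO,40,2,0.02,39,103,5,2.64
PS,40,6,0.09,39,151,9,3.87
PL,40,28,0.47,40,217,9,5.43
SP,40,6,0.07,40,162,9,4.05
SM,40,33,0.63,40,231,9,5.78
SA,40,19,0.20,37,100,9,2.70
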