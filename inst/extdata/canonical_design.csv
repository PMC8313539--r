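parameter,index,value
a,1,0.063
a,2,0.063
a,3,0.071999999999999995
a,4,0.083000000000000004
a,5,0.106
ter,1,0.35599999999999998
ter,2,0.35599999999999998
ter,3,0.38200000000000001
ter,4,0.39300000000000002
ter,5,0.41399999999999998
p_o,1,0.73499999999999999
p_o,2,0.20100000000000001
p_o,3,0
p_o,4,0
p_o,5,0
v,1,0.108
v,2,0.17499999999999999
v,3,0.28299999999999997
v,4,0.42599999999999999
v,5,0.54600000000000004
eta,NA,0.184
sz,NA,0.036999999999999998
st,NA,0.129
mu_g,NA,0.26200000000000001
s_g,NA,0.050999999999999997
s,NA,0.10000000000000001
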