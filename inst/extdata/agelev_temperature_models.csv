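response,class,variable,intercept,linear,quadratic
age_elev,all,bio1,49.575,3.262,-0.132
age_elev,all,bio5,15.796,5.917,-0.166
age_elev,all,bio6,67.38,0.532,-0.057
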