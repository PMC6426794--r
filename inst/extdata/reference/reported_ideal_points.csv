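experiment,concentration,time_min,ev_pred,cf_pred
NaOCl,1.62,13.96,99.98,0.00
CaClO2,10.00,7.43,95.01,0.00
HgCl2,0.32,2.50,68.65,14.58
AgNO3,0.92,14.50,55.49,38.17
H2O2,11.56,15.00,97.34,0.00
NS,10.00,11.63,88.10,6.31
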