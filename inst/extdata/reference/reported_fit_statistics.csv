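target,phase,r2,rmse
CF,train,0.97,4.54
CF,test,0.97,4.96
EV,train,0.94,6.93
EV,test,0.94,7.17
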