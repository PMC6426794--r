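output,input,vsr,rank
CF,naocl_pct,3.25,2
CF,caclo2_pct,2.28,4
CF,hgcl2_pct,3.11,3
CF,agno3_pct,1.12,7
CF,h2o2_pct,1.89,5
CF,ns_mgL,1.71,6
CF,time_min,3.48,1
EV,naocl_pct,2.34,2
EV,caclo2_pct,2.12,3
EV,hgcl2_pct,1.63,4
EV,agno3_pct,1.35,7
EV,h2o2_pct,1.56,5
EV,ns_mgL,1.50,6
EV,time_min,2.49,1
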