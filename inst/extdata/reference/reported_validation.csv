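treatment,cf_observed,ev_observed
1.62% NaOCl x 13.96 min,0.00,100.00
10% CaClO2 x 7.43 min,0.00,95.55
0.32% HgCl2 x 2.5 min,13.33,62.22
11.56% H2O2 x 15 min,2.22,95.55
0.92% AgNO3 x 14.5 min,26.67,71.11
10 mg/L NS x 15 min,8.89,88.89
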