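group1,group2,visual_mean,visual_sd,F12,P12,F21,P21,F_avg,P_avg,GED,FS
Type 2,Type 7,3.6,0.7,0.96,0.37,0.92,0.38,0.94,0.38,97,0.97
Type 2,Type 8,3.6,0.8,0.94,0.37,0.91,0.28,0.93,0.33,91,0.98
Type 2,Type 10,3.3,0.8,0.96,0.37,0.91,0.31,0.94,0.34,100,0.98
Type 7,Type 8,2.1,0.9,0.95,0.40,0.98,0.28,0.97,0.34,100,0.99
Type 7,Type 10,2.7,0.7,0.97,0.40,0.97,0.31,0.97,0.36,96,0.99
Type 8,Type 10,2.0,0.9,0.98,0.30,0.95,0.33,0.97,0.32,58,1.00
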