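group1,group2,visual_mean,visual_sd,F12,P12,F21,P21,F_avg,P_avg,GED,FS
SVOB,NoSVOB,1.6,0.8,1.00,0.63,0.71,0.84,0.86,0.74,39,0.97
Age >=50,Age <50,2.2,1.1,0.69,0.86,1.00,0.52,0.85,0.69,34,0.96
Birad12,Birad3-6,1.9,0.9,0.82,0.59,0.57,0.73,0.70,0.66,36,0.90
NoSVOB,Age <50,2.6,0.9,0.70,0.86,1.00,0.60,0.85,0.73,39,0.95
SVOB,Birad12,0.0,0.0,0.78,0.75,0.81,0.75,0.80,0.75,4,0.98
2Birad12,2Birad3-6,3.5,0.9,0.80,0.56,0.56,0.52,0.68,0.54,69,0.96
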