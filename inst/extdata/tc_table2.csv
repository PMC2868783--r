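pH,ucb_uM,theta,fs_HB,fs_B,theta_calc
7.23,34.0,-11.80,0.1661,0.5790,-13.42
7.35,4.6,-12.60,0.1474,0.6780,-11.06
8.13,4.6,0.69,0.0345,0.9550,1.50
8.15,34.0,1.90,0.0330,0.9570,1.66
9.12,4.6,5.10,0.0037,0.9946,4.75
9.35,34.0,5.38,0.00217,0.9962,4.91
11.60,34.0,5.50,0.000012,0.9986,5.13
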