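scenario_id,legumes,processed_meat,red_meat,white_meat
S1,0.00,2.78,5.56,4.17
S2M1,0.67,1.39,4.89,3.47
S2M2,0.83,1.39,4.89,4.00
S2M3,1.11,2.50,4.89,4.00
S5,5.56,1.39,2.78,3.47
S7M1,6.89,1.39,1.44,3.47
S8M1,7.56,1.39,0.78,3.47
S9M2,8.89,0.56,0.78,2.97
S9M3,10.00,0.28,0.11,2.81
S10,11.11,0.00,0.00,2.78
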