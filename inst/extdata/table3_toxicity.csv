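sample_time,glucose_g_L,ibp_remaining_mg_L,tu,toxicity_level,source_table
0 days,0,10,2.25,acute toxicity,table3
28 days,0,6.0,0.60,slight acute toxicity,table3
28 days,1,1.0,0.87,slight acute toxicity,table3
28 days,3,0,0.68,slight acute toxicity,table3
0 days,0,50,3.98,acute toxicity,table3
28 days,1,31.8,5.31,acute toxicity,table3
28 days,3,19.2,5.80,acute toxicity,table3
0 days,0,100,5.68,acute toxicity,table3
28 days,1,83.4,8.72,acute toxicity,table3
28 days,3,51.6,17.9,high acute toxicity,table3
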