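ibp_mg_L,glucose_g_L,model,K1,K2,tb,alpha,beta,dt50_d,extent_pct,r2,err_scaled,chi2_calculated,source_table,note
1,1,FOMC,NA,NA,NA,2.653,17.547,5.2,90.3,0.977,4.01,3.293,table2,
1,3,HS,1.812,1.374,0.1,NA,NA,0.5,100.0,1.000,0.03,0.396,table2,
5,1,FOMC,NA,NA,NA,0.599,3.623,7.9,73.8,0.991,1.94,0.861,table2,
5,3,HS,0.526,5.711,2.6,NA,NA,1.3,100.0,1.000,0.0004,0.010,table2,
10,0,FOMC,NA,NA,NA,0.233,3.462,64.5,40.0,0.971,1.99,0.568,table2,
10,1,FOMC,NA,NA,NA,2.906,23.561,6.3,81.7,0.944,6.63,3.102,table2,
10,3,SFO,0.501,NA,NA,NA,NA,1.4,100.0,0.983,4.04,11.428,table2,
50,1,FOMC,NA,NA,NA,0.307,4.699,40.2,36.3,0.855,5.48,3.566,table2,
50,3,FOMC,NA,NA,NA,0.154,0.036,3.2,61.5,0.993,1.49,0.513,table2,
100,1,FOMC,NA,NA,NA,0.071,1.769,30506,16.6,0.888,1.81,0.345,table2,printed as 30 506 with a comma; stored reading the comma as a thousands separator (decimal-comma reading 30.506 d would contradict the closed form)
100,3,FOMC,NA,NA,NA,0.073,0.002,29.0,48.4,0.997,0.79,0.112,table2,
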