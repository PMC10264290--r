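case,outlet,lumen,n_branches,target_flow_mL_s,cfd_flow_mL_s,r_total_mmHg_per_mL_s,rho,c_mL_per_mmHg
D,BT,none,1,17.10,17.69,5.77,0.030,0.235
D,LCC,none,1,3.84,3.97,25.67,0.030,0.053
D,LSA,none,1,6.69,6.98,14.75,0.030,0.092
D,CT,none,1,16.31,16.14,6.05,0.056,0.223
D,SMA,none,1,14.09,13.86,7.00,0.056,0.192
D,LRA,none,1,16.59,15.63,5.94,0.280,0.227
D,RRA,none,1,12.64,12.25,7.80,0.280,0.173
D,LEI,none,1,9.61,9.60,10.26,0.056,0.131
D,LII,none,1,4.76,4.76,20.72,0.056,0.065
D,REI,none,1,5.21,5.41,18.95,0.056,0.071
D,RII,none,1,3.01,3.17,32.79,0.056,0.041
D_min,BT,none,1,17.10,17.39,5.77,0.030,0.235
D_min,LCC,none,1,3.84,3.88,25.67,0.030,0.053
D_min,LSA,none,1,6.69,6.80,14.75,0.030,0.092
D_min,S1,FL,7,5.50,5.09,17.93,0.056,0.075
D_min,S2,TL,11,7.97,7.43,12.37,0.056,0.109
D_min,S3,FL,2,2.11,1.89,46.79,0.056,0.029
D_min,CT,none,1,12.38,12.39,7.97,0.056,0.170
D_min,SMA,none,1,10.70,10.72,9.22,0.056,0.147
D_min,LRA,none,1,12.20,12.10,8.09,0.280,0.167
D_min,RRA,none,1,9.20,9.23,10.72,0.280,0.126
D_min,S4,FL,8,4.29,3.98,23.01,0.056,0.059
D_min,IMA,TL,1,1.93,1.71,51.12,0.056,0.026
D_min,LEI,none,1,6.77,6.87,13.57,0.056,0.093
D_min,LII,none,1,3.35,3.38,27.39,0.056,0.046
D_min,REI,none,1,3.40,3.46,26.97,0.056,0.047
D_min,RII,none,1,1.97,1.99,46.67,0.056,0.027
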