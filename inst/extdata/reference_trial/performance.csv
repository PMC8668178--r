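# Growth performance and carcass characteristics: least squares means by
# dose (mg/kg DM). Contrast p-values printed as bounds ("<0.001") are
# stored as their upper bounds.
variable,unit,d0,d1_38,d5_5,d22,sem,p_dose_sex,p_dose,p_c_1_38,p_c_5_5,p_c_22
initial_bw_kg,kg,451,454,455,452,10.0,0.996,0.937,NA,NA,NA
final_bw_kg,kg,567,583,582,582,19.4,0.916,0.257,NA,NA,NA
dmi_kg,kg,8.8,9.2,8.8,8.8,0.56,0.980,0.585,NA,NA,NA
adg_kg,kg,1.27,1.42,1.39,1.43,0.126,0.724,0.075,0.027,0.067,0.023
gf,kg:kg,0.144,0.156,0.158,0.163,0.0071,0.856,0.031,0.065,0.033,0.005
hcw_kg,kg,349,364,365,365,11.7,0.865,0.035,0.019,0.014,0.014
dressing_pct,%,61.5,62.4,62.7,62.8,0.34,0.738,0.002,0.006,0.001,0.001
adj_fat_cm,cm,1.28,1.15,1.24,1.19,0.119,0.994,0.579,NA,NA,NA
lm_area_cm2,cm2,88.4,94.8,96.1,96.8,1.78,0.063,0.001,0.001,0.001,0.001
marbling,score,623,573,560,562,16.7,0.979,0.058,0.051,0.018,0.022
yield_grade,grade,2.68,2.37,2.41,2.25,0.164,0.816,0.155,NA,NA,NA
kph_pct,%,1.96,1.99,1.96,1.61,0.066,0.802,0.002,0.742,0.981,0.001
lean_maturity,score,162,163,167,163,3.5,0.731,0.262,NA,NA,NA
skeletal_maturity,score,172,170,170,172,1.9,0.585,0.592,NA,NA,NA
overall_maturity,score,169,168,169,168,2.5,0.639,0.805,NA,NA,NA
wbsf_14d_kg,kg,2.48,2.79,2.92,2.75,0.117,0.620,0.017,0.022,0.003,0.039
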