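# Interim-period cumulative NH3 emissions and body weights: least squares
# means by dose (mg/kg DM). Contrast p-values printed as bounds ("<0.001")
# are stored as their upper bounds.
variable,unit,d0,d1_38,d5_5,d22,sem,p_dose_sex,p_dose,p_c_1_38,p_c_5_5,p_c_22
bw_initial_kg,kg,451,454,455,452,10.0,0.996,0.937,NA,NA,NA
bw_day7_kg,kg,464,469,470,469,10.4,0.968,0.935,NA,NA,NA
bw_day14_kg,kg,474,484,484,478,12.3,0.962,0.655,NA,NA,NA
bw_day28_kg,kg,496,508,506,501,12.2,0.990,0.627,NA,NA,NA
bw_day56_kg,kg,529,545,542,539,15.2,0.974,0.411,NA,NA,NA
bw_final_kg,kg,567,583,582,582,19.4,0.916,0.257,NA,NA,NA
nh3_g_0_7,g,415,394,387,326,49,0.746,0.022,0.439,0.300,0.004
nh3_g_0_14,g,953,835,801,699,106,0.802,0.006,0.062,0.020,0.001
nh3_g_0_28,g,2097,1783,1686,1563,265,0.573,0.006,0.027,0.006,0.001
nh3_g_0_56,g,4619,4089,3888,3763,540,0.420,0.019,0.050,0.011,0.004
nh3_g_0_91,g,7783,7093,6860,6751,855,0.281,0.052,0.076,0.023,0.013
nh3_gkg_0_7,g/kg,0.89,0.84,0.82,0.70,0.106,0.619,0.003,0.278,0.139,0.001
nh3_gkg_0_14,g/kg,2.01,1.73,1.66,1.47,0.223,0.698,0.001,0.010,0.002,0.001
nh3_gkg_0_28,g/kg,4.21,3.53,3.33,3.13,0.509,0.463,0.001,0.004,0.001,0.001
nh3_gkg_0_56,g/kg,8.66,7.50,7.14,6.99,0.871,0.258,0.001,0.004,0.001,0.001
nh3_gkg_0_91,g/kg,13.6,12.2,11.7,11.6,1.19,0.161,0.004,0.009,0.002,0.001
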