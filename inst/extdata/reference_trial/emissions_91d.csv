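# 91-d cumulative gas emissions and weight-standardized emissions:
# least squares means by dose (mg/kg DM), pooled SEM, interaction and dose
# p-values, and planned control-contrast p-values. Contrast p-values
# printed as bounds ("<0.001") are stored as their upper bounds; blank
# cells mean the contrast was not performed.
variable,gas,unit,d0,d1_38,d5_5,d22,sem,p_dose_sex,p_dose,p_c_1_38,p_c_5_5,p_c_22
final_bw_kg,NA,kg,567,583,582,582,19.4,0.916,0.257,NA,NA,NA
hcw_kg,NA,kg,349,364,365,365,11.7,0.865,0.035,0.019,0.014,0.014
nh3_total_g,NH3,g/animal,7783,7093,6860,6751,855,0.281,0.052,0.076,0.023,0.013
nh3_per_kg_bw,NH3,g/kg,13.6,12.1,11.7,11.6,1.19,0.161,0.004,0.009,0.002,0.001
nh3_per_kg_hcw,NH3,g/kg,22.3,19.5,18.7,18.5,1.97,0.147,0.001,0.004,0.001,0.001
ch4_total_g,CH4,g/animal,10466,10692,10763,10476,638,0.712,0.895,NA,NA,NA
ch4_per_kg_bw,CH4,g/kg,18.4,18.3,18.5,18.0,1.06,0.439,0.858,NA,NA,NA
ch4_per_kg_hcw,CH4,g/kg,30.0,29.3,29.5,28.7,1.81,0.376,0.601,NA,NA,NA
co2_total_kg,CO2,kg/animal,720,758,734,755,47.3,0.616,0.302,NA,NA,NA
co2_per_kg_bw,CO2,g/kg,1268,1299,1261,1299,61.3,0.322,0.268,NA,NA,NA
co2_per_kg_hcw,CO2,g/kg,2061,2081,2013,2070,107.8,0.269,0.331,NA,NA,NA
h2s_total_g,H2S,g/animal,20.6,19.9,20.3,20.0,6.04,0.581,0.975,NA,NA,NA
h2s_per_kg_bw,H2S,g/kg,0.035,0.033,0.035,0.033,0.0110,0.417,0.905,NA,NA,NA
h2s_per_kg_hcw,H2S,g/kg,0.057,0.055,0.055,0.055,0.0176,0.379,0.776,NA,NA,NA
n2o_total_g,N2O,g/animal,-27.4,-36.8,-36.4,-34.7,10.2,0.279,0.627,NA,NA,NA
n2o_per_kg_bw,N2O,g/kg,-0.046,-0.062,-0.060,-0.060,0.0154,0.306,0.693,NA,NA,NA
n2o_per_kg_hcw,N2O,g/kg,-0.075,-0.097,-0.095,-0.095,0.0264,0.311,0.742,NA,NA,NA
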