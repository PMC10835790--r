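quantity,printed,tol_units
subject_LCIV_mean_area_avg,72.6,1
subject_LCIV_mean_area_std,32.7,1
control_LCIV_mean_area_avg,131.8,1
control_LCIV_mean_area_std,7.2,1
LCIV_mean_area_p_between,0.01218,1
subject_LCIV_mean_flow_avg,0.635,1
subject_LCIV_mean_flow_std,0.367,1
control_LCIV_mean_flow_avg,0.914,1
control_LCIV_mean_flow_std,0.225,1
LCIV_mean_flow_p_between,0.24318,50
subject_LCIV_mean_shear_avg,550,1
subject_LCIV_mean_shear_std,103,1
control_LCIV_mean_shear_avg,75,1
control_LCIV_mean_shear_std,37,1
LCIV_mean_shear_p_between,0.00013,1
subject_LCIV_q1_shear_avg,245,1
subject_LCIV_q1_shear_std,90,1
control_LCIV_q1_shear_avg,27,1
control_LCIV_q1_shear_std,11,1
LCIV_q1_shear_p_between,0.00296,1
subject_LCIV_q3_shear_avg,810,1
subject_LCIV_q3_shear_std,142,1
control_LCIV_q3_shear_avg,114,1
control_LCIV_q3_shear_std,59,1
LCIV_q3_shear_p_between,0.00010,1
subject_LCIV_mean_peak_shear_avg,1653,1
subject_LCIV_mean_peak_shear_std,451,1
control_LCIV_mean_peak_shear_avg,256,1
control_LCIV_mean_peak_shear_std,165,1
LCIV_mean_peak_shear_p_between,0.00114,1
subject_RCIV_mean_area_avg,196.3,1
subject_RCIV_mean_area_std,124.4,1
control_RCIV_mean_area_avg,138.5,1
control_RCIV_mean_area_std,24.6,1
RCIV_mean_area_p_between,0.39748,50
subject_RCIV_mean_flow_avg,1.487,1
subject_RCIV_mean_flow_std,0.495,1
control_RCIV_mean_flow_avg,0.816,1
control_RCIV_mean_flow_std,0.292,1
RCIV_mean_flow_p_between,0.05836,2
subject_RCIV_mean_shear_avg,113,1
subject_RCIV_mean_shear_std,48,1
control_RCIV_mean_shear_avg,54,1
control_RCIV_mean_shear_std,11,1
RCIV_mean_shear_p_between,0.05209,1
subject_RCIV_q1_shear_avg,39,1
subject_RCIV_q1_shear_std,10,1
control_RCIV_q1_shear_avg,25,1
control_RCIV_q1_shear_std,6,1
RCIV_q1_shear_p_between,0.05312,1
subject_RCIV_q3_shear_avg,153,1
subject_RCIV_q3_shear_std,69,1
control_RCIV_q3_shear_avg,72,1
control_RCIV_q3_shear_std,14,1
RCIV_q3_shear_p_between,0.06149,1
subject_RCIV_mean_peak_shear_avg,545,1
subject_RCIV_mean_peak_shear_std,293,1
control_RCIV_mean_peak_shear_avg,213,1
control_RCIV_mean_peak_shear_std,95,1
RCIV_mean_peak_shear_p_between,0.07478,1
subject_shear_ratio_avg,6.56,1
subject_shear_ratio_std,0.90,1
control_shear_ratio_avg,1.43,1
control_shear_ratio_std,0.60,1
shear_ratio_p_between,0.00008,1
subject_mean_area_p_paired,0.104,1
subject_mean_flow_p_paired,0.117,1
subject_mean_shear_p_paired,0.0009,1
control_mean_area_p_paired,0.700,2
control_mean_flow_p_paired,0.718,1
control_mean_shear_p_paired,0.329,1
ratio_of_ratios,4.6,1
age_years_p,0.019,1
height_m_p,0.731,1
weight_kg_p,0.154,1
bmi_p,0.129,1
respiratory_period_s_p,0.781,1
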