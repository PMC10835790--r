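group,patient,vessel,metric,value
Subject,1,LCIV,mean_area,76.2
Subject,2,LCIV,mean_area,30.6
Subject,3,LCIV,mean_area,73.4
Subject,4,LCIV,mean_area,110.3
Subject,1,LCIV,mean_flow,1.154
Subject,2,LCIV,mean_flow,0.308
Subject,3,LCIV,mean_flow,0.469
Subject,4,LCIV,mean_flow,0.608
Subject,1,LCIV,mean_shear,571
Subject,2,LCIV,mean_shear,480
Subject,3,LCIV,mean_shear,688
Subject,4,LCIV,mean_shear,462
Subject,1,LCIV,q1_shear,236
Subject,2,LCIV,q1_shear,267
Subject,3,LCIV,q1_shear,348
Subject,4,LCIV,q1_shear,130
Subject,1,LCIV,q3_shear,862
Subject,2,LCIV,q3_shear,672
Subject,3,LCIV,q3_shear,986
Subject,4,LCIV,q3_shear,720
Subject,1,LCIV,mean_peak_shear,1688
Subject,2,LCIV,mean_peak_shear,1191
Subject,3,LCIV,mean_peak_shear,2257
Subject,4,LCIV,mean_peak_shear,1475
Subject,1,RCIV,mean_area,120.4
Subject,2,RCIV,mean_area,172.3
Subject,3,RCIV,mean_area,113.8
Subject,4,RCIV,mean_area,378.7
Subject,1,RCIV,mean_flow,0.900
Subject,2,RCIV,mean_flow,1.609
Subject,3,RCIV,mean_flow,1.352
Subject,4,RCIV,mean_flow,2.086
Subject,1,RCIV,mean_shear,89
Subject,2,RCIV,mean_shear,103
Subject,3,RCIV,mean_shear,183
Subject,4,RCIV,mean_shear,78
Subject,1,RCIV,q1_shear,35
Subject,2,RCIV,q1_shear,41
Subject,3,RCIV,q1_shear,51
Subject,4,RCIV,q1_shear,28
Subject,1,RCIV,q3_shear,132
Subject,2,RCIV,q3_shear,146
Subject,3,RCIV,q3_shear,249
Subject,4,RCIV,q3_shear,85
Subject,1,RCIV,mean_peak_shear,254
Subject,2,RCIV,mean_peak_shear,385
Subject,3,RCIV,mean_peak_shear,923
Subject,4,RCIV,mean_peak_shear,616
Subject,1,LCIV/RCIV,shear_ratio,7.21
Subject,2,LCIV/RCIV,shear_ratio,5.59
Subject,3,LCIV/RCIV,shear_ratio,6.02
Subject,4,LCIV/RCIV,shear_ratio,7.43
Control,1,LCIV,mean_area,142.1
Control,2,LCIV,mean_area,131.5
Control,3,LCIV,mean_area,126.0
Control,4,LCIV,mean_area,127.8
Control,1,LCIV,mean_flow,1.184
Control,2,LCIV,mean_flow,1.010
Control,3,LCIV,mean_flow,0.694
Control,4,LCIV,mean_flow,0.767
Control,1,LCIV,mean_shear,131
Control,2,LCIV,mean_shear,58
Control,3,LCIV,mean_shear,53
Control,4,LCIV,mean_shear,59
Control,1,LCIV,q1_shear,43
Control,2,LCIV,q1_shear,22
Control,3,LCIV,q1_shear,18
Control,4,LCIV,q1_shear,23
Control,1,LCIV,q3_shear,202
Control,2,LCIV,q3_shear,80
Control,3,LCIV,q3_shear,81
Control,4,LCIV,q3_shear,92
Control,1,LCIV,mean_peak_shear,503
Control,2,LCIV,mean_peak_shear,187
Control,3,LCIV,mean_peak_shear,159
Control,4,LCIV,mean_peak_shear,175
Control,1,RCIV,mean_area,105.6
Control,2,RCIV,mean_area,140.9
Control,3,RCIV,mean_area,165.3
Control,4,RCIV,mean_area,142.3
Control,1,RCIV,mean_flow,0.578
Control,2,RCIV,mean_flow,0.680
Control,3,RCIV,mean_flow,1.238
Control,4,RCIV,mean_flow,0.767
Control,1,RCIV,mean_shear,59
Control,2,RCIV,mean_shear,39
Control,3,RCIV,mean_shear,64
Control,4,RCIV,mean_shear,55
Control,1,RCIV,q1_shear,22
Control,2,RCIV,q1_shear,18
Control,3,RCIV,q1_shear,26
Control,4,RCIV,q1_shear,33
Control,1,RCIV,q3_shear,69
Control,2,RCIV,q3_shear,58
Control,3,RCIV,q3_shear,92
Control,4,RCIV,q3_shear,69
Control,1,RCIV,mean_peak_shear,316
Control,2,RCIV,mean_peak_shear,100
Control,3,RCIV,mean_peak_shear,260
Control,4,RCIV,mean_peak_shear,174
Control,1,LCIV/RCIV,shear_ratio,2.21
Control,2,LCIV/RCIV,shear_ratio,1.58
Control,3,LCIV/RCIV,shear_ratio,0.84
Control,4,LCIV/RCIV,shear_ratio,1.09
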