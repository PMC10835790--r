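group,patient,variable,value
Subject,1,age_years,25
Subject,2,age_years,41
Subject,3,age_years,52
Subject,4,age_years,47
Control,1,age_years,85
Control,2,age_years,62
Control,3,age_years,62
Control,4,age_years,61
Subject,1,sex,F
Subject,2,sex,F
Subject,3,sex,M
Subject,4,sex,F
Control,1,sex,M
Control,2,sex,F
Control,3,sex,F
Control,4,sex,F
Subject,1,race,White
Subject,2,race,White
Subject,3,race,White
Subject,4,race,White
Control,1,race,White
Control,2,race,White
Control,3,race,White
Control,4,race,White
Subject,1,height_m,1.59
Subject,2,height_m,1.73
Subject,3,height_m,1.83
Subject,4,height_m,1.65
Control,1,height_m,1.78
Control,2,height_m,1.65
Control,3,height_m,1.65
Control,4,height_m,1.63
Subject,1,weight_kg,56.3
Subject,2,weight_kg,104.2
Subject,3,weight_kg,73.0
Subject,4,weight_kg,81.6
Control,1,weight_kg,93.2
Control,2,weight_kg,112.0
Control,3,weight_kg,80.4
Control,4,weight_kg,111.4
Subject,1,bmi,22.3
Subject,2,bmi,34.9
Subject,3,bmi,21.8
Subject,4,bmi,29.9
Control,1,bmi,29.4
Control,2,bmi,41.1
Control,3,bmi,29.5
Control,4,bmi,42.1
Subject,1,respiratory_period_s,3
Subject,2,respiratory_period_s,3
Subject,3,respiratory_period_s,3.75
Subject,4,respiratory_period_s,3.2
Control,1,respiratory_period_s,3
Control,2,respiratory_period_s,3.75
Control,3,respiratory_period_s,3.5
Control,4,respiratory_period_s,3
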