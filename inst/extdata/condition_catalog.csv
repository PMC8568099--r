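condition_code,age_band,sex,prevalence,services
diabetes,16-30,any,0.03,fresh_produce;weight_management;fitness
diabetes,31-45,any,0.08,fresh_produce;weight_management;fitness
diabetes,46-65,any,0.17,fresh_produce;weight_management;fitness
diabetes,66-94,any,0.25,fresh_produce;weight_management;fitness
hypertension,16-30,any,0.05,fresh_produce;walking_group
hypertension,31-45,any,0.15,fresh_produce;walking_group
hypertension,46-65,any,0.35,fresh_produce;walking_group
hypertension,66-94,any,0.55,fresh_produce;walking_group
obesity,16-30,any,0.2,weight_management;group_exercise;fresh_produce
obesity,31-45,any,0.3,weight_management;group_exercise;fresh_produce
obesity,46-65,any,0.35,weight_management;group_exercise;fresh_produce
obesity,66-94,any,0.3,weight_management;group_exercise;fresh_produce
depression,16-30,female,0.18,mental_health;spiritual_services
depression,31-45,female,0.15,mental_health;spiritual_services
depression,46-65,female,0.12,mental_health;spiritual_services
depression,66-94,female,0.1,mental_health;spiritual_services
depression,16-30,male,0.1,mental_health;spiritual_services
depression,31-45,male,0.08,mental_health;spiritual_services
depression,46-65,male,0.07,mental_health;spiritual_services
depression,66-94,male,0.06,mental_health;spiritual_services
smoking,16-30,any,0.15,smoking_cessation
smoking,31-45,any,0.18,smoking_cessation
smoking,46-65,any,0.15,smoking_cessation
smoking,66-94,any,0.08,smoking_cessation
food_insecurity,16-30,any,0.25,food_pantry;fresh_produce
food_insecurity,31-45,any,0.2,food_pantry;fresh_produce
food_insecurity,46-65,any,0.15,food_pantry;fresh_produce
food_insecurity,66-94,any,0.12,food_pantry;fresh_produce
housing_instability,16-30,any,0.15,housing_support
housing_instability,31-45,any,0.1,housing_support
housing_instability,46-65,any,0.06,housing_support
housing_instability,66-94,any,0.04,housing_support
asthma,16-30,any,0.1,smoking_cessation;home_care
asthma,31-45,any,0.08,smoking_cessation;home_care
asthma,46-65,any,0.07,smoking_cessation;home_care
asthma,66-94,any,0.06,smoking_cessation;home_care
arthritis,16-30,any,0.02,walking_group;senior_services
arthritis,31-45,any,0.07,walking_group;senior_services
arthritis,46-65,any,0.25,walking_group;senior_services
arthritis,66-94,any,0.45,walking_group;senior_services
social_isolation,16-30,any,0.05,spiritual_services;senior_services;group_exercise
social_isolation,31-45,any,0.05,spiritual_services;senior_services;group_exercise
social_isolation,46-65,any,0.08,spiritual_services;senior_services;group_exercise
social_isolation,66-94,any,0.2,spiritual_services;senior_services;group_exercise
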