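activity_id,code,label,activity_class,p_level,decision_type,location_policy,mapped_services,clinic_trigger
1,sleeping,Sleeping,daily_living,none,none,home,"",FALSE
2,grooming,Washing and grooming,daily_living,none,none,home,"",FALSE
3,eating_home,Eating at home,daily_living,low,none,home,"",FALSE
4,housework,Housework,daily_living,low,none,home,"",FALSE
5,relaxing_home,Relaxing at home,daily_living,low,none,home,"",FALSE
6,phone_socializing,Talking on the phone,daily_living,low,none,home,"",FALSE
7,work_main,"Working, main job",daily_living,low,none,work,"",FALSE
8,work_social,Socializing as part of job,daily_living,high,none,work,"",FALSE
9,school_attend,Attending class,daily_living,low,none,school,"",FALSE
10,grocery_shopping,Grocery shopping,daily_living,medium,none,out_of_home,"",FALSE
11,errands,Errands and shopping,daily_living,medium,none,out_of_home,"",FALSE
12,socializing_out,Socializing away from home,daily_living,medium,none,out_of_home,"",FALSE
13,eating_out,Eating out,daily_living,medium,none,out_of_home,"",FALSE
14,helping_hh_adults,Helping household adults,daily_living,medium,none,home,"",FALSE
15,fitness,Exercise and fitness,health_maintenance,medium,AB,service_site,fitness;group_exercise;walking_group,FALSE
16,spiritual_practice,Spiritual practice,health_maintenance,medium,AB,service_site,spiritual_services,FALSE
17,weight_mgmt_class,Weight management class,health_maintenance,medium,AB,service_site,weight_management,FALSE
18,self_care_health,Health-related self-care,health_maintenance,medium,AB,service_site,mental_health;smoking_cessation,FALSE
19,produce_shopping,Getting fresh fruits and vegetables,health_maintenance,medium,AB,service_site,fresh_produce;food_pantry,FALSE
20,medical_care_self,Obtaining medical care,health_maintenance,high,none,service_site,primary_care,TRUE
21,medical_care_hh,Obtaining medical and care services for household adult,health_maintenance,high,none,service_site,primary_care,TRUE
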