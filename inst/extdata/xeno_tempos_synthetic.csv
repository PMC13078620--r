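"species","group","tempo_hz","modality","medium"
"synthetic_bird_01","bird",11.25,"sound","air"
"synthetic_bird_02","bird",4.77,"sound","air"
"synthetic_bird_03","bird",9,"sound","air"
"synthetic_bird_04","bird",2.66,"sound","air"
"synthetic_bird_05","bird",5.23,"sound","air"
"synthetic_bird_06","bird",7.53,"sound","air"
"synthetic_bird_07","bird",5.09,"sound","air"
"synthetic_bird_08","bird",6.71,"sound","air"
"synthetic_bird_09","bird",4.62,"sound","air"
"synthetic_bird_10","bird",1.35,"sound","air"
"synthetic_bat_01","bat",2.21,"sound","air"
"synthetic_bat_02","bat",5.32,"sound","air"
"synthetic_bat_03","bat",4.61,"sound","air"
"synthetic_bat_04","bat",0.87,"sound","air"
"synthetic_bat_05","bat",1.18,"sound","air"
"synthetic_bat_06","bat",2.03,"sound","air"
"synthetic_bat_07","bat",2.89,"sound","air"
"synthetic_bat_08","bat",3.93,"sound","air"
"synthetic_bat_09","bat",10.5,"sound","air"
"synthetic_bat_10","bat",7.34,"sound","air"
"synthetic_frog_01","frog",3.88,"sound","air"
"synthetic_frog_02","frog",1.45,"sound","air"
"synthetic_frog_03","frog",5.85,"sound","air"
"synthetic_frog_04","frog",11.42,"sound","air"
"synthetic_frog_05","frog",0.46,"sound","air"
"synthetic_frog_06","frog",0.98,"sound","air"
"synthetic_frog_07","frog",9.84,"sound","air"
"synthetic_frog_08","frog",3.4,"sound","air"
"synthetic_frog_09","frog",0.9,"sound","air"
"synthetic_frog_10","frog",0.89,"sound","air"
"synthetic_grasshopper_01","grasshopper",1.03,"sound","air"
"synthetic_grasshopper_02","grasshopper",3.64,"sound","air"
"synthetic_grasshopper_03","grasshopper",1.34,"sound","air"
"synthetic_grasshopper_04","grasshopper",1.83,"sound","air"
"synthetic_grasshopper_05","grasshopper",1.24,"sound","air"
"synthetic_grasshopper_06","grasshopper",1.65,"sound","air"
"synthetic_grasshopper_07","grasshopper",3.5,"sound","air"
"synthetic_grasshopper_08","grasshopper",22.88,"sound","air"
"synthetic_grasshopper_09","grasshopper",9.02,"sound","air"
"synthetic_grasshopper_10","grasshopper",7.51,"sound","air"
"synthetic_land_mammal_01","land-mammal",2.84,"sound","air"
"synthetic_land_mammal_02","land-mammal",3.73,"sound","air"
"synthetic_land_mammal_03","land-mammal",7.63,"sound","air"
"synthetic_land_mammal_04","land-mammal",2.35,"sound","air"
"synthetic_land_mammal_05","land-mammal",2.17,"sound","air"
"synthetic_land_mammal_06","land-mammal",0.81,"sound","air"
"synthetic_land_mammal_07","land-mammal",0.47,"sound","air"
"synthetic_land_mammal_08","land-mammal",1.3,"sound","air"
"synthetic_land_mammal_09","land-mammal",1.88,"sound","air"
"synthetic_land_mammal_10","land-mammal",6.87,"sound","air"
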