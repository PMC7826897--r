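"parameter_id","value","fish_index","unit"
"m_personnel_training","2","",""
"m_daily_check","0","",""
"m_treatment_journal","1","",""
"m_target_value_sheet","2","",""
"m_emergency_concept","2","",""
"m_hygiene_concept","1","",""
"m_mortality_documentation","2","",""
"m_biomass_documentation","2","",""
"m_predator_protection","2","",""
"m_plant_cleanliness","1","",""
"m_stocking_density","0","",""
"m_sorting","0","",""
"m_slaughter","1","",""
"m_feeding_interval_rate","0","",""
"m_feed_type","0","",""
"m_disturbances","0","",""
"m_ambient_light","NA","",""
"m_tank_light","1","",""
"w_carbonate_hardness","347","",""
"w_total_suspended_solids","20","",""
"w_ammonium_tan","NA","",""
"w_ammonia_nh3","NA","",""
"w_nitrite","NA","",""
"w_nitrate","NA","",""
"w_ph","7.61","",""
"w_conductivity","640","",""
"w_temperature","14.8","",""
"w_oxygen","5.9","",""
"w_oxygen_saturation","62","",""
"w_carbon_dioxide","5.5","",""
"w_total_gas_pressure","100","",""
"w_water_velocity","0.3","",""
"fg_aggression","1","",""
"fg_territoriality","0","",""
"fg_apathy","0","",""
"fg_isolation","0","",""
"fg_scratching","1","",""
"fg_surfacing","0","",""
"fg_air_gulping","1","",""
"fg_ventilation_rate","2","",""
"fg_fleeing","0","",""
"fg_fin_position","0","",""
"fg_balance","0","",""
"fg_body_colour","0","",""
"fg_feeding","0","",""
"fg_jaw_deformations","4","",""
"fg_gill_cover_deformations","2","",""
"fg_spinal_deformations","0","",""
"fg_eye_injuries","1","",""
"fg_skin_injuries","1","",""
"fg_fin_injuries","2","",""
"fg_fungal_infections","0","",""
"fe_body_condition","1.6","",""
"fe_mucus_pathogens","0","",""
"fe_spinal_deformation","0","",""
"fe_jaw_deformation","2","",""
"fe_mouth_injury","1","",""
"fe_skin_alterations","1","",""
"fe_skin_fungus","0","",""
"fe_skin_injury","0","",""
"fe_cataract","0","",""
"fe_eye_injury","1","",""
"fe_exophthalmia","0","",""
"fe_pectoral_fins","1","",""
"fe_ventral_fins","0","",""
"fe_anal_fin","0","",""
"fe_caudal_fin","0","",""
"fe_dorsal_fin","1","",""
"fe_gill_cover","1","",""
"fe_gills","1","",""
"fi_heart","0","",""
"fi_kidney","0","",""
"fi_spleen","0","",""
"fi_liver","0","",""
"fi_intestines","0","",""
"fi_muscles","0","",""
"fi_reproductive_organs","0","",""
"fi_gill_lamellae","2","",""
"fi_gill_pathogens","1","",""
"fi_body_cavity","0","",""
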