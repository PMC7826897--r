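"parameter_id","value","fish_index","unit"
"m_personnel_training","0","",""
"m_daily_check","0","",""
"m_treatment_journal","1","",""
"m_target_value_sheet","1","",""
"m_emergency_concept","1","",""
"m_hygiene_concept","1","",""
"m_mortality_documentation","1","",""
"m_biomass_documentation","0","",""
"m_predator_protection","NA","",""
"m_plant_cleanliness","0","",""
"m_stocking_density","1","",""
"m_sorting","0","",""
"m_slaughter","0","",""
"m_feeding_interval_rate","0","",""
"m_feed_type","0","",""
"m_disturbances","1","",""
"m_ambient_light","0","",""
"m_tank_light","0","",""
"w_carbonate_hardness","310","",""
"w_total_suspended_solids","10","",""
"w_ammonium_tan","0.79","",""
"w_ammonia_nh3","0.005","",""
"w_nitrite","0.12","",""
"w_nitrate","7.29","",""
"w_ph","7.5","",""
"w_conductivity","711","",""
"w_temperature","11.5","",""
"w_oxygen","11","",""
"w_oxygen_saturation","108","",""
"w_carbon_dioxide","21.8","",""
"w_total_gas_pressure","102","",""
"w_water_velocity","0.3","",""
"fg_aggression","0","",""
"fg_territoriality","0","",""
"fg_apathy","0","",""
"fg_isolation","0","",""
"fg_scratching","0","",""
"fg_surfacing","2","",""
"fg_air_gulping","0","",""
"fg_ventilation_rate","0","",""
"fg_fleeing","0","",""
"fg_fin_position","0","",""
"fg_balance","0","",""
"fg_body_colour","1","",""
"fg_feeding","1","",""
"fg_jaw_deformations","0","",""
"fg_gill_cover_deformations","0","",""
"fg_spinal_deformations","0","",""
"fg_eye_injuries","1","",""
"fg_skin_injuries","2","",""
"fg_fin_injuries","2","",""
"fg_fungal_infections","0","",""
"fe_body_condition","1.5","",""
"fe_mucus_pathogens","0","",""
"fe_spinal_deformation","0","",""
"fe_jaw_deformation","1","",""
"fe_mouth_injury","1","",""
"fe_skin_alterations","0","",""
"fe_skin_fungus","0","",""
"fe_skin_injury","0","",""
"fe_cataract","0","",""
"fe_eye_injury","1","",""
"fe_exophthalmia","0","",""
"fe_pectoral_fins","0","",""
"fe_ventral_fins","1","",""
"fe_anal_fin","0","",""
"fe_caudal_fin","0","",""
"fe_dorsal_fin","1","",""
"fe_gill_cover","0","",""
"fe_gills","0","",""
"fi_heart","0","",""
"fi_kidney","0","",""
"fi_spleen","0","",""
"fi_liver","0","",""
"fi_intestines","0","",""
"fi_muscles","0","",""
"fi_reproductive_organs","0","",""
"fi_gill_lamellae","0","",""
"fi_gill_pathogens","0","",""
"fi_body_cavity","0","",""
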