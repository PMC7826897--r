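# Builds the six validation-farm fixtures under inst/extdata/farms/:
# one measurement CSV per farm (module M, FG, FE, FI entries as interval
# indices; module W entries as measured values), farm_metadata.csv, and
# farm_observations.csv with the raw morphometric / water-chemistry
# readings that feed the derived measures (standard length, total length,
# body weight, TAN, pH, temperature, dissolved oxygen) plus the reported
# condition factors and ammonia values.
#
# Run from the package root:  Rscript data-raw/farms.R

dir.create("inst/extdata/farms", recursive = TRUE, showWarnings = FALSE)

meta <- data.frame(
  farm_id = 1:6,
  location = c("indoor", "indoor", "outdoor", "outdoor", "indoor", "indoor"),
  system = c("RAS", "RAS", "FTS", "FTS", "RAS", "RAS"),
  species = c("rainbow trout", "rainbow trout", "rainbow trout",
              "rainbow trout", "pikeperch", "pikeperch"),
  purpose = c("grow-out", "grow-out", "grow-out", "restocking",
              "grow-out", "grow-out"),
  timestamp = "2019-07-01",
  stringsAsFactors = FALSE)
write.csv(meta, "inst/extdata/farms/farm_metadata.csv", row.names = FALSE)

# per-parameter entries, farms 1..6 ("NA" = parameter does not apply)
V <- function(...) as.character(c(...))
rows <- list(
  # farm management (interval indices)
  m_personnel_training      = V(1, 0, 2, 1, 0, 0),
  m_daily_check             = V(0, 0, 0, 0, 0, 0),
  m_treatment_journal       = V(0, 1, 1, 1, 0, 1),
  m_target_value_sheet      = V(1, 1, 2, 1, 0, 1),
  m_emergency_concept       = V(1, 1, 2, 1, 0, 1),
  m_hygiene_concept         = V(1, 1, 1, 1, 0, 1),
  m_mortality_documentation = V(1, 1, 2, 2, 0, 1),
  m_biomass_documentation   = V(1, 0, 2, 1, 0, 1),
  m_predator_protection     = V(NA, NA, 2, 1, NA, NA),
  m_plant_cleanliness       = V(0, 0, 1, 0, 0, 0),
  m_stocking_density        = V(0, 1, 0, 0, 1, 1),
  m_sorting                 = V(0, 0, 0, 1, 0, 0),
  m_slaughter               = V(0, 0, 1, 0, 0, 0),
  m_feeding_interval_rate   = V(0, 0, 0, 0, 0, 0),
  m_feed_type               = V(0, 0, 0, 0, 0, 0),
  m_disturbances            = V(1, 1, 0, 1, 0, 0),
  m_ambient_light           = V(0, 0, NA, NA, 0, 0),
  m_tank_light              = V(0, 0, 1, 1, 0, 0),
  # water quality (measured values)
  w_carbonate_hardness      = V(194, 310, 347, 128, NA, 28.2),
  w_total_suspended_solids  = V(26, 10, 20, 5, 12, 15.9),
  w_ammonium_tan            = V(0.04, 0.79, NA, NA, 0.03, 0.21),
  w_ammonia_nh3             = V(0.001, 0.005, NA, NA, 0, 0),
  w_nitrite                 = V(0.04, 0.12, NA, NA, 0.01, 0.05),
  w_nitrate                 = V(6.18, 7.29, NA, NA, 6.53, 73.1),
  w_ph                      = V(7.84, 7.5, 7.61, 7.75, 7.5, 6.4),
  w_conductivity            = V(487, 711, 640, 254, NA, 8030),
  w_temperature             = V(16.9, 11.5, 14.8, 7.4, 23.7, 22.8),
  w_oxygen                  = V(9.57, 11, 5.9, 9.2, 8.5, 9.1),
  w_oxygen_saturation       = V(106, 108, 62, 82, 108, 113),
  w_carbon_dioxide          = V(6.1, 21.8, 5.5, 1.6, 2, 7.5),
  w_total_gas_pressure      = V(99, 102, 100, 100, 100, 100),
  w_water_velocity          = V(0.3, 0.3, 0.3, 0.4, 0.3, 0.3),
  # fish group behaviour (interval indices)
  fg_aggression             = V(0, 0, 1, 0, 0, 0),
  fg_territoriality         = V(0, 0, 0, 0, 0, 0),
  fg_apathy                 = V(0, 0, 0, 0, 0, 0),
  fg_isolation              = V(1, 0, 0, 0, 0, 1),
  fg_scratching             = V(0, 0, 1, 0, 0, 0),
  fg_surfacing              = V(0, 2, 0, 0, 0, 0),
  fg_air_gulping            = V(0, 0, 1, 0, 0, 0),
  fg_ventilation_rate       = V(0, 0, 2, 0, 0, 0),
  fg_fleeing                = V(0, 0, 0, 0, 0, 0),
  fg_fin_position           = V(0, 0, 0, 0, 0, 0),
  fg_balance                = V(0, 0, 0, 0, 0, 0),
  fg_body_colour            = V(0, 1, 0, 0, 1, 0),
  fg_feeding                = V(0, 1, 0, 0, 0, 0),
  fg_jaw_deformations       = V(0, 0, 4, 0, 0, 0),
  fg_gill_cover_deformations = V(0, 0, 2, 0, 0, 0),
  fg_spinal_deformations    = V(0, 0, 0, 0, 0, 0),
  fg_eye_injuries           = V(1, 1, 1, 0, 2, 2),
  fg_skin_injuries          = V(2, 2, 1, 0, 0, 1),
  fg_fin_injuries           = V(2, 2, 2, 1, 2, 2),
  fg_fungal_infections      = V(0, 0, 0, 0, 0, 0),
  # fish external appearance (farm-average interval indices; the body
  # condition factor is the reported numeric value)
  fe_body_condition         = V(1.8, 1.5, 1.6, 1.4, 0.96, 0.84),
  fe_mucus_pathogens        = V(0, 0, 0, 0, 0, 0),
  fe_spinal_deformation     = V(0, 0, 0, 0, 0, 0),
  fe_jaw_deformation        = V(0, 1, 2, 0, 0, 0),
  fe_mouth_injury           = V(1, 1, 1, 0, 1, 1),
  fe_skin_alterations       = V(1, 0, 1, 0, 0, 0),
  fe_skin_fungus            = V(0, 0, 0, 0, 0, 0),
  fe_skin_injury            = V(0, 0, 0, 0, 0, 0),
  fe_cataract               = V(1, 0, 0, 0, 1, 1),
  fe_eye_injury             = V(1, 1, 1, 0, 1, 1),
  fe_exophthalmia           = V(0, 0, 0, 0, 0, 0),
  fe_pectoral_fins          = V(0, 0, 1, 1, 1, 1),
  fe_ventral_fins           = V(1, 1, 0, 1, 1, 1),
  fe_anal_fin               = V(0, 0, 0, 1, 1, 1),
  fe_caudal_fin             = V(0, 0, 0, 0, 1, 1),
  fe_dorsal_fin             = V(0, 1, 1, 0, 2, 2),
  fe_gill_cover             = V(0, 0, 1, 0, 1, 1),
  fe_gills                  = V(1, 0, 1, 0, 0, 1),
  # fish internal appearance (farm-average interval indices)
  fi_heart                  = V(0, 0, 0, 0, 0, 0),
  fi_kidney                 = V(0, 0, 0, 0, 0, 0),
  fi_spleen                 = V(0, 0, 0, 0, 0, 0),
  fi_liver                  = V(1, 0, 0, 0, 0, 0),
  fi_intestines             = V(1, 0, 0, 0, 0, 0),
  fi_muscles                = V(0, 0, 0, 0, 0, 0),
  fi_reproductive_organs    = V(1, 0, 0, 0, 0, 0),
  fi_gill_lamellae          = V(1, 0, 2, 0, 1, 1),
  fi_gill_pathogens         = V(0, 0, 1, 0, 0, 0),
  fi_body_cavity            = V(0, 0, 0, 0, 0, 0)
)
stopifnot(all(vapply(rows, length, 0L) == 6L), length(rows) == 80L)

for (farm in 1:6) {
  df <- data.frame(parameter_id = names(rows),
                   value = vapply(rows, `[[`, "", farm),
                   fish_index = "", unit = "",
                   stringsAsFactors = FALSE, row.names = NULL)
  df$value[is.na(df$value)] <- "NA"
  write.csv(df, sprintf("inst/extdata/farms/farm%d.csv", farm),
            row.names = FALSE)
}

obs <- data.frame(
  farm_id = 1:6,
  standard_length_cm = c(19.5, 19.6, 11.6, 25, 25.2, 28.7),
  total_length_cm = c(21.7, 21.7, 13.5, 27.6, 26.1, 32.4),
  body_weight_g = c(132, 111, 25.3, 218, 154, 198),
  body_condition_factor = c(1.8, 1.5, 1.6, 1.4, 0.96, 0.84),
  tan_mg_l = c(0.04, 0.79, NA, NA, 0.03, 0.21),
  ammonia_nh3_mg_l = c(0.001, 0.005, NA, NA, 0, 0),
  ph = c(7.84, 7.5, 7.61, 7.75, 7.5, 6.4),
  temperature_c = c(16.9, 11.5, 14.8, 7.4, 23.7, 22.8),
  dissolved_oxygen_mg_l = c(9.57, 11, 5.9, 9.2, 8.5, 9.1),
  oxygen_saturation_pct = c(106, 108, 62, 82, 108, 113),
  stringsAsFactors = FALSE)
write.csv(obs, "inst/extdata/farms/farm_observations.csv",
          row.names = FALSE)
cat("wrote", length(list.files("inst/extdata/farms")),
    "files under inst/extdata/farms\n")
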