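# Builds inst/extdata/default_config.yaml, the shipped default scoring
# registry: 80 parameters in five modules (M 18, W 14, FG 20, FE 18, FI 10).
#
# Structure (module membership, parameter names, interval counts, the
# index-0-optimal convention, exponents) follows the published model
# layout.  The per-interval numbers are reconstructed defaults, NOT a
# literature transcription: parameter scores are spaced linearly from 0 to
# -1 over each parameter's severity ranks, score weights scale linearly
# from 1 to 5 over the ranks, and every parameter weight is 3.  Numeric
# water-quality boundaries follow common freshwater grow-out guidance.
#
# Run from the package root:  Rscript data-raw/default_config.R

for (f in list.files("R", full.names = TRUE)) source(f)

sw_scale <- function(k, K) as.integer(round(1 + 4 * k / K))

ord_param <- function(id, name, module, labels, per_fish = FALSE, PW = 3L,
                      applicability = character()) {
  n <- length(labels)
  parameter_def(id, name, module,
                interval_table(index = seq_len(n) - 1L,
                               PS = -(seq_len(n) - 1L) / (n - 1L),
                               SW = sw_scale(seq_len(n) - 1L, n - 1L),
                               label = labels),
                kind = "ordinal", PW = PW, per_fish = per_fish,
                applicability = applicability)
}

num_param <- function(id, name, module, unit, ivs, per_fish = FALSE,
                      PW = 3L, applicability = character()) {
  # ivs: data.frame(lower, upper, PS) in severity order (row 1 = optimal)
  K <- nrow(ivs) - 1L
  parameter_def(id, name, module, unit = unit,
                interval_table(index = seq_len(nrow(ivs)) - 1L,
                               PS = ivs$PS,
                               SW = sw_scale(seq_len(nrow(ivs)) - 1L, K),
                               lower = ivs$lower, upper = ivs$upper),
                kind = "numeric", PW = PW, per_fish = per_fish,
                applicability = applicability)
}

iv <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(lower = m[, 1], upper = m[, 2], PS = m[, 3])
}

lab_m  <- c("adequate", "partial", "inadequate")
lab_fg <- c("none", "minimal", "mild", "moderate", "marked", "severe")
lab_ff <- c("none", "mild", "moderate", "severe")

third <- 1 / 3

modules <- list(
  module_def("M",  "farm management",          SWE = 0,   PWE = 1.7),
  module_def("W",  "water quality",            SWE = 1.7, PWE = 1.7),
  module_def("FG", "fish group behaviour",     SWE = 1.7, PWE = 1.7),
  module_def("FE", "fish external appearance", SWE = 1.7, PWE = 1.7),
  module_def("FI", "fish internal appearance", SWE = 1.7, PWE = 1.7)
)

m_names <- c(
  m_personnel_training     = "Personnel training",
  m_daily_check            = "Daily check",
  m_treatment_journal      = "Treatment journal",
  m_target_value_sheet     = "Target value sheet",
  m_emergency_concept      = "Emergency concept",
  m_hygiene_concept        = "Hygiene concept",
  m_mortality_documentation = "Mortality documentation",
  m_biomass_documentation  = "Biomass documentation",
  m_predator_protection    = "Predator protection",
  m_plant_cleanliness      = "Plant cleanliness",
  m_stocking_density       = "Stocking density",
  m_sorting                = "Sorting",
  m_slaughter              = "Slaughter",
  m_feeding_interval_rate  = "Feeding interval/rate",
  m_feed_type              = "Feed type",
  m_disturbances           = "Disturbances",
  m_ambient_light          = "Ambient light",
  m_tank_light             = "Tank light"
)
m_applic <- list(m_predator_protection = c("location:outdoor"),
                 m_ambient_light = c("location:indoor"))
m_params <- lapply(names(m_names), function(id)
  ord_param(id, m_names[[id]], "M", lab_m,
            applicability = m_applic[[id]] %||% character()))

w_params <- list(
  num_param("w_carbonate_hardness", "Carbonate hardness", "W", "mg/L CaCO3",
            iv(50, 400, 0,   400, Inf, -third,   20, 50, -2 * third,
               0, 20, -1)),
  num_param("w_total_suspended_solids", "Total suspended solids", "W",
            "mg/L", iv(0, 25, 0,   25, 80, -third,   80, 200, -2 * third,
                       200, Inf, -1)),
  num_param("w_ammonium_tan", "Ammonium", "W", "mg/L TAN",
            iv(0, 1, 0,   1, 2, -third,   2, 5, -2 * third,   5, Inf, -1)),
  num_param("w_ammonia_nh3", "Ammonia", "W", "mg/L NH3-N",
            iv(0, 0.01, 0,   0.01, 0.02, -third,   0.02, 0.05, -2 * third,
               0.05, Inf, -1)),
  num_param("w_nitrite", "Nitrite", "W", "mg/L NO2-N",
            iv(0, 0.1, 0,   0.1, 0.3, -third,   0.3, 1, -2 * third,
               1, Inf, -1)),
  num_param("w_nitrate", "Nitrate", "W", "mg/L NO3-N",
            iv(0, 100, 0,   100, 200, -third,   200, 500, -2 * third,
               500, Inf, -1)),
  num_param("w_ph", "pH", "W", "",
            iv(6.5, 8.5, 0,   6.0, 6.5, -third,   8.5, 9.5, -third,
               5.0, 6.0, -2 * third,   9.5, 10.5, -2 * third,
               0, 5.0, -1,   10.5, 14, -1)),
  num_param("w_conductivity", "Conductivity", "W", "uS/cm",
            iv(100, 1500, 0,   1500, 5000, -third,   0, 100, -2 * third,
               5000, 10000, -2 * third,   10000, 100000, -1)),
  num_param("w_temperature", "Temperature", "W", "degC",
            iv(8, 26, 0,   4, 8, -third,   26, 30, -2 * third,
               0, 4, -1,   30, 40, -1)),
  num_param("w_oxygen", "Oxygen", "W", "mg/L O2",
            iv(8, 25, 0,   6, 8, -third,   4, 6, -2 * third,   0, 4, -1)),
  num_param("w_oxygen_saturation", "Oxygen saturation", "W", "% O2",
            iv(80, 120, 0,   120, 150, -third,   60, 80, -2 * third,
               0, 60, -1,   150, 400, -1)),
  num_param("w_carbon_dioxide", "Carbon dioxide", "W", "mg/L CO2",
            iv(0, 7, 0,   7, 15, -third,   15, 30, -2 * third,
               30, 200, -1)),
  num_param("w_total_gas_pressure", "Total gas pressure", "W", "%",
            iv(95, 103, 0,   103, 110, -third,   85, 95, -2 * third,
               110, 200, -1,   0, 85, -1)),
  num_param("w_water_velocity", "Water velocity", "W", "body lengths/s",
            iv(0.5, 2, 0,   0.2, 0.5, -third,   2, 3, -2 * third,
               0, 0.2, -1,   3, 10, -1))
)

fg_names <- c(
  fg_aggression = "Aggression", fg_territoriality = "Territoriality",
  fg_apathy = "Apathy", fg_isolation = "Isolation",
  fg_scratching = "Scratching", fg_surfacing = "Surfacing",
  fg_air_gulping = "Air gulping", fg_ventilation_rate = "Ventilation rate",
  fg_fleeing = "Fleeing", fg_fin_position = "Fin position",
  fg_balance = "Balance", fg_body_colour = "Body colour",
  fg_feeding = "Feeding", fg_jaw_deformations = "Jaw deformations",
  fg_gill_cover_deformations = "Gill cover deformations",
  fg_spinal_deformations = "Spinal deformations",
  fg_eye_injuries = "Eye injuries", fg_skin_injuries = "Skin injuries",
  fg_fin_injuries = "Fin injuries", fg_fungal_infections = "Fungal infections"
)
fg_params <- lapply(names(fg_names), function(id)
  ord_param(id, fg_names[[id]], "FG", lab_fg))

fe_ord_names <- c(
  fe_mucus_pathogens = "Mucus pathogens",
  fe_spinal_deformation = "Spinal deformation",
  fe_jaw_deformation = "Jaw deformation", fe_mouth_injury = "Mouth injury",
  fe_skin_alterations = "Skin alterations", fe_skin_fungus = "Skin fungus",
  fe_skin_injury = "Skin injury", fe_cataract = "Cataract",
  fe_eye_injury = "Eye injury", fe_exophthalmia = "Exophthalmia",
  fe_pectoral_fins = "Pectoral fins", fe_ventral_fins = "Ventral fins",
  fe_anal_fin = "Anal fin", fe_caudal_fin = "Caudal fin",
  fe_dorsal_fin = "Dorsal fin", fe_gill_cover = "Gill cover",
  fe_gills = "Gills"
)
fe_params <- c(
  list(num_param("fe_body_condition", "Body condition factor", "FE", "",
                 iv(0.9, 1.55, 0,   1.55, 1.8, -third,   0.7, 0.9, -third,
                    1.8, 2.5, -2 * third,   0.4, 0.7, -2 * third,
                    2.5, 5, -1,   0.05, 0.4, -1),
                 per_fish = TRUE)),
  lapply(names(fe_ord_names), function(id)
    ord_param(id, fe_ord_names[[id]], "FE", lab_ff, per_fish = TRUE))
)

fi_names <- c(
  fi_heart = "Heart", fi_kidney = "Kidney", fi_spleen = "Spleen",
  fi_liver = "Liver", fi_intestines = "Intestines", fi_muscles = "Muscles",
  fi_reproductive_organs = "Reproductive organs",
  fi_gill_lamellae = "Gill lamellae", fi_gill_pathogens = "Gill pathogens",
  fi_body_cavity = "Body cavity"
)
fi_params <- lapply(names(fi_names), function(id)
  ord_param(id, fi_names[[id]], "FI", lab_ff, per_fish = TRUE))

cfg <- model_config(
  modules, c(m_params, w_params, fg_params, fe_params, fi_params),
  provenance = paste(
    "default registry (synthetic reconstruction): module layout, parameter",
    "names, interval counts and exponents follow the published model;",
    "numeric boundaries follow general freshwater grow-out guidance;",
    "PS linear 0..-1, SW linear 1..5 over severity ranks, PW = 3",
    "throughout.  Numeric bounds are half-open [lower, upper)."))

stopifnot(length(cfg$parameters) == 80L, nrow(cfg$modules) == 5L)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
yaml::write_yaml(config_to_list(cfg), "inst/extdata/default_config.yaml",
                 precision = 12L)
cat("wrote inst/extdata/default_config.yaml with",
    length(cfg$parameters), "parameters\n")
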