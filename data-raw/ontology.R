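# Builds inst/extdata/ontology.json: the fourteen welfare needs, the 80
# selected model parameters (criteria all met, module assigned), two
# classic counter-examples that fail the selection criteria (VSI,
# hematocrit), and an illustrative excerpt of correlation triples around
# the needs respiration and nutrition (five shown parameters each; the
# full published network is much denser).
#
# Run from the package root:  Rscript data-raw/ontology.R

for (f in list.files("R", full.names = TRUE)) source(f)

needs <- data.frame(
  id = c("respiration", "osmotic_regulation", "thermal_regulation",
         "water_quality", "hygiene", "health", "body_care", "nutrition",
         "safety", "movement", "social_contact", "rest", "exploration",
         "reproduction"),
  name = c("Respiration", "Osmotic regulation", "Thermal regulation",
           "Water quality", "Hygiene", "Health", "Body care", "Nutrition",
           "Safety", "Movement", "Social contact", "Rest", "Exploration",
           "Reproduction"),
  description = c(
    "able to perform gas exchange over the gills",
    "able to maintain homeostasis of cellular fluids",
    "able to maintain body temperature for successful metabolism",
    "spared from abiotic adverse influences (toxins, particles, metabolites, ions, gases)",
    "spared from biotic adverse influences (parasites, bacteria, viruses)",
    "spared from disease, illness, malfunction, or malformation",
    "able to perform body care",
    "able to take up food of right quality and quantity",
    "able to avoid perceived danger and physical injury",
    "able to move freely",
    "able to have contact to conspecifics",
    "able to rest",
    "able to seek and find external stimuli",
    "able to perform reproductive behaviour when sexually mature"),
  stringsAsFactors = FALSE)

cfg <- load_model_config("inst/extdata/default_config.yaml")
model_pars <- data.frame(
  id = names(cfg$parameters),
  name = vapply(cfg$parameters, `[[`, "", "name"),
  relevant = TRUE, practicable = TRUE, reliable = TRUE,
  module = vapply(cfg$parameters, `[[`, "", "module"),
  stringsAsFactors = FALSE)

excluded <- data.frame(
  id = c("vsi", "hematocrit"),
  name = c("Viscerosomatic index", "Hematocrit"),
  # VSI: fat sampling is tedious on-farm and optimum thresholds unclear;
  # hematocrit: responds to handling within minutes and the welfare link
  # is confounded by many physiological processes.
  relevant = c(FALSE, FALSE),
  practicable = c(FALSE, FALSE),
  reliable = c(TRUE, FALSE),
  module = NA_character_,
  stringsAsFactors = FALSE)

triples <- data.frame(
  need = c(rep("respiration", 5), rep("nutrition", 5)),
  parameter = c("fe_jaw_deformation", "w_ammonium_tan", "fi_gill_pathogens",
                "fg_ventilation_rate", "hematocrit",
                "m_feed_type", "fe_cataract", "vsi", "fe_jaw_deformation",
                "w_ammonium_tan"),
  relation = c("affects", "affects", "affects", "affected_by",
               "affected_by",
               "affects", "affected_by", "affected_by", "affects",
               "affects"),
  stringsAsFactors = FALSE)

ont <- ontology_graph(needs, rbind(model_pars, excluded), triples)
export_graph(ont, "inst/extdata/ontology.json", format = "json")
cat("wrote inst/extdata/ontology.json:", nrow(ont$needs), "needs,",
    nrow(ont$parameters), "parameters,", nrow(ont$triples), "triples\n")
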