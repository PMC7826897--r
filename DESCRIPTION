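Package: fishwelfare
Title: Modular Fish Welfare Assessment for Aquaculture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to assess fish welfare on aquaculture farms with a
    modular, configuration-driven grading model.  A welfare ontology links
    fourteen fundamental needs to measurable parameters; a scoring registry
    maps each measured parameter onto discretised parameter scores and
    severity weights; and an exponent-weighted grading equation turns a
    farm visit's measurements into one grade per module (farm management,
    water quality, fish group behaviour, fish external and internal
    appearance), each categorised as critical, poor, acceptable or good.
    Includes water-chemistry and morphometric helpers (unionized ammonia,
    dissolved-oxygen saturation, Fulton's condition factor), validated
    CSV/JSON/YAML input and output, fixture generation for property
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
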