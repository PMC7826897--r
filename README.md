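# fishwelfare

Modular, configuration-driven fish-welfare assessment for aquaculture
farms.

Welfare assessment on fish farms has to turn dozens of heterogeneous
observations — water chemistry, husbandry practice, shoal behaviour, the
external and internal appearance of sampled fish — into something a
farmer, veterinarian or scientist can act on. `fishwelfare` implements a
complete assessment model for that task:

* a **welfare ontology**: fourteen fundamental needs (respiration,
  nutrition, safety, ...) linked to measurable parameters by typed
  correlation triples, with the three admission criteria (relevant,
  practicable, reliable) used to select parameters into the model;
* a **scoring registry** of 80 parameters in five modules — farm
  management (M), water quality (W), fish group behaviour (FG), fish
  external appearance (FE) and fish internal appearance (FI).  Every
  parameter maps its measured value onto an interval carrying a
  parameter score `PS ∈ [−1, 0]` and a score weight `SW ∈ {1..5}`
  (stressor severity), and carries a parameter weight `PW ∈ {1..5}`
  (relative importance);
* the **grading equation**.  Each module is graded independently over
  its measured parameters:

  ```
  MG = 1 + Σᵢ PSᵢ · SWᵢ^SWE · PWᵢ^PWE  /  Σᵢ SWᵢ^SWE · PWᵢ^PWE
  ```

  with exponents `SWE = PWE = 1.7` (`SWE = 0` for module M).  The grade
  lies in `[0, 1]` and is categorised as critical `[0, 0.25)`, poor
  `[0.25, 0.5)`, acceptable `[0.5, 0.75)` or good `[0.75, 1]`;
* **derived measures**: unionized ammonia (NH₃-N) from TAN/pH/temperature
  via the freshwater Emerson equilibrium, percent dissolved-oxygen
  saturation via the Benson–Krause solubility form, and Fulton's body
  condition factor `K = 100·W/L³` from standard length and weight;
* validated **I/O** (YAML/JSON configs, CSV/JSON assessments, JSON
  reports with config checksums, GraphML ontology export), six packaged
  farm-visit fixtures, a deterministic synthetic-assessment generator,
  and a command-line interface.

The shipped default registry reproduces the published model's structure
exactly (module layout, parameter names, interval counts, exponents,
index-0-optimal convention); its per-interval scores and weights are a
documented reconstruction (linear score spacing, default weight 3) — see
`?default_model_config` and the vignette.

## Worked example

```r
library(fishwelfare)

cfg <- default_model_config()   # 80 parameters, 5 modules
farm <- load_farm_fixture(3)    # outdoor flow-through trout farm
grades <- assess(farm, cfg)
print(grades)
#> assessment: 3 / outdoor / FTS / rainbow trout / grow-out / 2019-07-01
#> module M   grade 0.50 (acceptable), 17 parameters scored, 1 missing
#> module W   grade 0.54 (acceptable), 10 parameters scored, 4 missing
#> module FG  grade 0.66 (acceptable), 20 parameters scored, 0 missing
#> module FE  grade 0.66 (acceptable), 18 parameters scored, 0 missing
#> module FI  grade 0.63 (acceptable), 10 parameters scored, 0 missing
```

Farm 3's low oxygen (5.9 mg/L), documentation gaps and gill findings pull
every module toward the lower end of "acceptable"; the four water
chemistry parameters that do not apply in a flow-through system were recorded `NA`
and are excluded from both the numerator and the normalisation, so the
grade stays comparable across farms.

Derived measures work standalone:

```r
fulton_condition_factor(132, 19.5)   # 1.780205  -> reported as 1.8
unionized_ammonia(0.79, 7.5, 11.5)   # 0.005177819 mg/L NH3-N
oxygen_saturation(9.1, 22.8)         # 105.7 %
```

The CLI wraps the same functions:

```sh
Rscript inst/cli/fishwelfare.R assess \
  --config inst/extdata/default_config.yaml \
  --assessment inst/extdata/farms/farm2.csv --out reports --format table
```

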