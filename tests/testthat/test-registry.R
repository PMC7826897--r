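# Scoring registry: config validation, interval resolution, overrides,
# serialization.

test_that("shipped default configuration loads and is fully populated", {
  cfg <- default_model_config()
  expect_s3_class(cfg, "welfare_config")
  expect_length(cfg$parameters, 80L)
  expect_equal(sort(cfg$modules$id), sort(c("M", "W", "FG", "FE", "FI")))
  counts <- table(vapply(cfg$parameters, `[[`, "", "module"))
  expect_equal(counts[["M"]], 18L)
  expect_equal(counts[["W"]], 14L)
  expect_equal(counts[["FG"]], 20L)
  expect_equal(counts[["FE"]], 18L)
  expect_equal(counts[["FI"]], 10L)
  # default exponents: 1.7 everywhere, score-weight exponent 0 for M
  expect_equal(cfg$modules$PWE, rep(1.7, 5))
  expect_equal(cfg$modules$SWE[cfg$modules$id == "M"], 0)
  expect_equal(sort(unique(cfg$modules$SWE)), c(0, 1.7))
})

test_that("validation rejects each class of broken configuration", {
  base <- tiny_config()
  broken <- list(
    "PS out of range" = function(cfg) {
      cfg$parameters$m_doc$intervals$PS[2] <- 0.2; cfg },
    "PW out of range" = function(cfg) {
      cfg$parameters$w_temp$PW <- 6L; cfg },
    "SW out of range" = function(cfg) {
      cfg$parameters$w_oxy$intervals$SW[3] <- 7; cfg },
    "interval 0 must have PS = 0" = function(cfg) {
      cfg$parameters$w_temp$intervals$PS[1] <- -0.1; cfg },
    "interval 0 must have SW = 1" = function(cfg) {
      cfg$parameters$w_temp$intervals$SW[1] <- 2; cfg },
    "PS must be non-increasing" = function(cfg) {
      cfg$parameters$w_temp$intervals$PS[3] <- -0.1; cfg },
    "SW must be non-decreasing" = function(cfg) {
      cfg$parameters$m_doc$intervals$SW[3] <- 2; cfg },
    "overlapping numeric intervals" = function(cfg) {
      cfg$parameters$w_temp$intervals$upper[1] <- 17; cfg },
    "gap in numeric coverage" = function(cfg) {
      cfg$parameters$w_temp$intervals$lower[2] <- 17; cfg },
    "unknown module reference" = function(cfg) {
      cfg$parameters$w_oxy$module <- "XX"; cfg },
    "duplicate parameter id" = function(cfg) {
      names(cfg$parameters)[2] <- "m_doc"
      cfg$parameters[[2]]$id <- "m_doc"; cfg },
    "fewer than two intervals" = function(cfg) {
      cfg$parameters$m_doc$intervals <-
        cfg$parameters$m_doc$intervals[1, , drop = FALSE]; cfg },
    "duplicate ordinal label" = function(cfg) {
      cfg$parameters$m_doc$intervals$label[3] <- "partial"; cfg })
  for (nm in names(broken)) {
    cfg_bad <- broken[[nm]](base)
    expect_error(validate_config(cfg_bad), "invalid model configuration",
                 info = nm)
  }
  # each message names the offending parameter
  cfg_bad <- broken[["PS out of range"]](base)
  expect_error(validate_config(cfg_bad), "m_doc")
})

test_that("numeric interval resolution is lower-inclusive and matches a linear scan", {
  cfg <- tiny_config()
  temp <- cfg$parameters$w_temp
  expect_equal(resolve_interval(temp, 12)$index, 0L)   # inside 10-16
  expect_equal(resolve_interval(temp, 16)$index, 1L)   # boundary -> upper interval
  expect_equal(resolve_interval(temp, 10)$index, 0L)   # lower bound inclusive
  expect_error(resolve_interval(temp, 45), "outside all configured intervals")
  expect_error(resolve_interval(temp, "warm"), "numeric value required")

  set.seed(11)
  all_params <- c(cfg$parameters[c("w_temp", "w_oxy")],
                  Filter(function(p) p$kind == "numeric",
                         default_model_config()$parameters))
  for (p in all_params) {
    lo <- min(p$intervals$lower[is.finite(p$intervals$lower)])
    hi <- max(p$intervals$upper[is.finite(p$intervals$upper)])
    vals <- runif(60, lo, hi)
    got <- vapply(vals, function(v) resolve_interval(p, v)$index, 0L)
    want <- vapply(vals, function(v) oracle_scan_interval(p, v), 0L)
    expect_equal(got, want, info = p$id)
  }
})

test_that("ordinal values resolve by index or exact label", {
  p <- tiny_config()$parameters$m_doc
  expect_equal(resolve_interval(p, 2)$PS, -1)
  expect_equal(resolve_interval(p, "partial")$index, 1L)
  expect_equal(resolve_interval(p, "1")$index, 1L)  # numeric string = index
  expect_error(resolve_interval(p, "pristine"), "unknown ordinal label")
  expect_error(resolve_interval(p, 9), "no interval with index")
})

test_that("configurations round-trip through YAML and JSON", {
  cfg <- default_model_config()
  for (fmt in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_model_config(cfg, path)
    back <- load_model_config(path)
    expect_equal(config_to_list(back), config_to_list(cfg),
                 tolerance = 1e-9, info = fmt)
  }
})

test_that("regulatory overrides substitute intervals without side effects", {
  cfg <- tiny_config()
  expect_identical(apply_overrides(cfg, list()), cfg)

  strict <- interval_table(index = 0:1, PS = c(0, -1), SW = c(1, 5),
                           lower = c(7, 0), upper = c(Inf, 7))
  ov <- regulatory_override("w_oxy", strict, jurisdiction = "CH",
                            rationale = "legal minimum dissolved oxygen")
  cfg2 <- apply_overrides(cfg, list(ov))
  expect_equal(cfg2$parameters$w_oxy$intervals, strict)
  expect_match(cfg2$provenance, "override\\[CH\\]: w_oxy")
  # original untouched, application idempotent
  expect_equal(nrow(cfg$parameters$w_oxy$intervals), 3L)
  expect_identical(apply_overrides(cfg2, list(ov)), cfg2)

  expect_error(apply_overrides(cfg, list(
    regulatory_override("nope", strict, "CH"))), "unknown parameter")
  bad <- interval_table(index = 0:1, PS = c(0, 0.5), SW = c(1, 5),
                        lower = c(7, 0), upper = c(Inf, 7))
  expect_error(apply_overrides(cfg, list(
    regulatory_override("w_oxy", bad, "CH"))), "PS out of range")
})
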