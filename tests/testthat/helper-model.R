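# Shared test fixtures and independent oracles.

# Direct, self-contained evaluation of the grading equation; kept separate
# from the engine so engine changes cannot silently drift past the tests.
oracle_module_grade <- function(PS, SW, PW, SWE, PWE) {
  terms_num <- PS * SW^SWE * PW^PWE
  terms_den <- SW^SWE * PW^PWE
  1 + sum(terms_num) / sum(terms_den)
}

# Linear scan over a parameter's intervals, independent of
# resolve_interval()'s lookup.
oracle_scan_interval <- function(param, value) {
  iv <- param$intervals
  for (i in seq_len(nrow(iv)))
    if (!is.na(iv$lower[i]) && iv$lower[i] <= value && value < iv$upper[i])
      return(iv$index[i])
  NA_integer_
}

# Small hand-built configuration: one management-style module (SWE = 0)
# and one water-style module with a numeric and an ordinal parameter.
tiny_config <- function() {
  model_config(
    modules = list(module_def("M", "management", SWE = 0, PWE = 1.7),
                   module_def("W", "water", SWE = 1.7, PWE = 1.7)),
    parameters = list(
      parameter_def("m_doc", "Documentation", "M",
                    interval_table(index = 0:2, PS = c(0, -0.5, -1),
                                   SW = c(1, 3, 5),
                                   label = c("adequate", "partial",
                                             "inadequate")),
                    kind = "ordinal"),
      parameter_def("w_temp", "Temperature", "W", unit = "degC",
                    interval_table(index = 0:3,
                                   PS = c(0, -1 / 3, -2 / 3, -1),
                                   SW = c(1, 2, 4, 5),
                                   lower = c(10, 16, 6, 20),
                                   upper = c(16, 20, 10, 40)),
                    kind = "numeric"),
      parameter_def("w_oxy", "Oxygen", "W", unit = "mg/L",
                    interval_table(index = 0:2, PS = c(0, -0.5, -1),
                                   SW = c(1, 3, 5),
                                   lower = c(8, 5, 0),
                                   upper = c(Inf, 8, 5)),
                    kind = "numeric")),
    provenance = "test fixture")
}

# Random scored-parameter table with n rows.
random_scored <- function(n, module = "W") {
  scored_df(parameter_id = sprintf("p%02d", seq_len(n)), module = module,
            PS = -round(runif(n), 3), SW = sample(1:5, n, replace = TRUE),
            PW = sample(1:5, n, replace = TRUE))
}

scored_df <- function(parameter_id, module, PS, SW, PW, n_fish = 1L) {
  data.frame(parameter_id = parameter_id, module = module,
             effective_PS = PS, effective_SW = SW, PW = PW,
             n_fish_averaged = n_fish, stringsAsFactors = FALSE)
}

# Two-parameter boundary data set whose grade crosses the critical/poor
# boundary (0.25) exactly where the exponent passes log(3)/log(s): with
# PS = (0, -1), equal PW and SW = (1, s), the grade is 1 - s^e/(1+s^e),
# which is below 0.25 iff s^e > 3.  Inverting for a chosen threshold
# exponent e* gives s = exp(log(3)/e*).
boundary_dataset <- function(e_star, target) {
  s <- exp(log(3) / e_star)
  list(scored = scored_df(c("a", "b"), "CAL", PS = c(0, -1),
                          SW = c(1, s), PW = c(3, 3)),
       target = target)
}
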