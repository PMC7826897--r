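# Derived measures: quantities that are calculated rather than measured
# during a farm visit — the unionized (toxic) ammonia fraction, percent
# dissolved-oxygen saturation, and Fulton's body condition factor.
# All functions are vectorized pure functions of their inputs.

# Range checks tolerate NA (an unmeasured input propagates to an NA
# result) but reject out-of-range and non-numeric values.
check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (!is.finite(x) | x < lo | x > hi)
  if (any(bad)) stop(what)
  invisible(x)
}

check_temperature <- function(temperature)
  check_range(temperature, 0, 40,
              "temperature must lie in the liquid-water range 0-40 degC")

#' Fulton's body condition factor
#'
#' K = 100 * W / L^3 with the body weight W in grams and the *standard*
#' length L (snout to caudal peduncle) in centimetres.  A unitless index
#' of nutritional state; scaling length by s and weight by s^3 leaves K
#' unchanged.
#'
#' @param body_weight Body weight in g (> 0).
#' @param standard_length Standard length in cm (> 0); not total length.
#' @return Condition factor K (unitless), unrounded.
#' @export
#' @examples
#' fulton_condition_factor(132, 19.5)   # about 1.78
fulton_condition_factor <- function(body_weight, standard_length) {
  check_range(standard_length, 1e-9, Inf,
              "standard_length must be a positive length in cm")
  check_range(body_weight, 1e-9, Inf,
              "body_weight must be a positive mass in g")
  100 * body_weight / standard_length^3
}

#' Ammonia dissociation exponent (freshwater)
#'
#' Temperature-dependent pKa of the ammonium/ammonia equilibrium in fresh
#' water: `pKa = 0.09018 + 2729.92 / T` with `T` in kelvin (Emerson et
#' al. 1975).  Salinity corrections are out of scope.
#'
#' @param temperature Water temperature in degC (0-40).
#' @return pKa (unitless).
#' @export
ammonia_pka <- function(temperature) {
  check_temperature(temperature)
  0.09018 + 2729.92 / (273.15 + temperature)
}

#' Unionized ammonia (NH3-N) from total ammonia nitrogen
#'
#' Partitions total ammonia nitrogen (TAN = NH4+-N + NH3-N) into its
#' unionized, gill-toxic fraction using the freshwater acid-base
#' equilibrium: `NH3-N = TAN / (1 + 10^(pKa - pH))`.  At `pH == pKa`
#' exactly half of the TAN is unionized; the result always lies in
#' `[0, TAN]`.
#'
#' @param TAN Total ammonia nitrogen in mg N/L (>= 0).
#' @param pH Water pH.
#' @param temperature Water temperature in degC (0-40).
#' @return NH3-N in mg/L, unrounded.
#' @export
#' @examples
#' unionized_ammonia(0.79, 7.5, 11.5)   # about 0.0052
unionized_ammonia <- function(TAN, pH, temperature) {
  check_range(TAN, 0, Inf, "TAN must be >= 0 mg N/L")
  check_range(pH, 0, 14, "pH must lie in [0, 14]")
  TAN / (1 + 10^(ammonia_pka(temperature) - pH))
}

#' Equilibrium dissolved-oxygen concentration in fresh water
#'
#' Benson-Krause closed form for the air-saturated oxygen concentration
#' (mg/L) at a given temperature, scaled to a non-standard barometric
#' pressure with the usual vapour-pressure / fugacity correction (as used
#' by standard solubility tables).
#'
#' @param temperature Water temperature in degC (0-40).
#' @param pressure Barometric pressure in atm (default 1).
#' @return Equilibrium concentration C_eq in mg/L.
#' @export
#' @examples
#' oxygen_solubility(20)   # about 9.09 mg/L
oxygen_solubility <- function(temperature, pressure = 1) {
  check_temperature(temperature)
  check_range(pressure, 1e-9, Inf, "pressure must be > 0 atm")
  TK <- 273.15 + temperature
  lnC <- -139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
    1.2438e10 / TK^3 - 8.621949e11 / TK^4
  C0 <- exp(lnC)                      # mg/L at 1 atm
  # vapour pressure of water (atm) and pressure correction
  Pwv <- exp(11.8571 - 3840.70 / TK - 216961 / TK^2)
  theta <- 0.000975 - 1.426e-5 * temperature + 6.436e-8 * temperature^2
  C0 * pressure * (1 - Pwv / pressure) * (1 - theta * pressure) /
    ((1 - Pwv) * (1 - theta))
}

#' Percent dissolved-oxygen saturation
#'
#' `100 * DO / C_eq(temperature, pressure)` with C_eq from
#' [oxygen_solubility()].  At fixed dissolved oxygen and pressure the
#' saturation increases with temperature (warmer water holds less
#' oxygen).
#'
#' @param dissolved_oxygen Measured dissolved oxygen in mg/L (>= 0).
#' @param temperature Water temperature in degC (0-40).
#' @param pressure Barometric pressure in atm (default 1); supply the
#'   site value for farms well above sea level.
#' @return Saturation in percent, unrounded.
#' @export
oxygen_saturation <- function(dissolved_oxygen, temperature, pressure = 1) {
  check_range(dissolved_oxygen, 0, Inf,
              "dissolved_oxygen must be >= 0 mg/L")
  100 * dissolved_oxygen / oxygen_solubility(temperature, pressure)
}

#' Round half away from zero
#'
#' Reporting helper matching the display convention of the assessment
#' tables (0.005 -> 0.01 at two decimals), unlike base R's round-half-even.
#' Internal computations are never rounded.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Round to significant figures, half away from zero
#'
#' @param x Numeric vector (non-zero entries).
#' @param digits Significant figures.
#' @return Rounded vector.
#' @export
signif_half_up <- function(x, digits = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  mag <- floor(log10(abs(x[nz])))
  out[nz] <- round_half_up(x[nz], digits - 1 - mag)
  out
}
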