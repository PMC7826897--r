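# Fixtures: the six packaged validation farms and a deterministic
# synthetic-assessment generator for property testing.

#' Load a packaged validation-farm assessment
#'
#' Six farm visits ship with the package (two indoor recirculating trout
#' farms, two outdoor flow-through trout farms, two indoor recirculating
#' pikeperch farms).  Water-quality entries are measured values; the
#' other modules carry the farm-average interval index per parameter, and
#' `NA` marks parameters that do not apply at the site (e.g. predator
#' protection indoors, ambient light outdoors).
#'
#' @param farm_id Integer 1..6.
#' @return A `welfare_assessment`.
#' @seealso [farm_observations()] for the underlying raw morphometric and
#'   water-chemistry readings.
#' @export
#' @examples
#' load_farm_fixture(3)
load_farm_fixture <- function(farm_id) {
  if (length(farm_id) != 1L || is.na(farm_id) || !farm_id %in% 1:6)
    stop("unknown farm id '", farm_id, "' (valid: 1..6)")
  dir <- system.file("extdata", "farms", package = "fishwelfare",
                     mustWork = TRUE)
  meta <- utils::read.csv(file.path(dir, "farm_metadata.csv"),
                          stringsAsFactors = FALSE)
  md <- meta[meta$farm_id == farm_id, , drop = FALSE]
  read_assessment(file.path(dir, sprintf("farm%d.csv", farm_id)),
                  format = "csv",
                  location = md$location, system = md$system,
                  species = md$species, purpose = md$purpose,
                  timestamp = md$timestamp,
                  farm_id = as.character(farm_id))
}

#' Raw per-farm observations behind the derived measures
#'
#' Mean standard/total length and body weight of the five fish sampled
#' per farm, the reported body condition factors, and the water-chemistry
#' readings (TAN, pH, temperature, dissolved oxygen, reported ammonia and
#' saturation) for the six packaged farms.
#'
#' @return A data frame with one row per farm.
#' @export
farm_observations <- function() {
  utils::read.csv(system.file("extdata", "farms", "farm_observations.csv",
                              package = "fishwelfare", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Specification for a synthetic assessment
#'
#' @param seed Integer seed; the same seed and spec always generate the
#'   identical assessment.
#' @param modules Module ids to populate (default: all in the config).
#' @param profile Severity profile: `"optimal"` (every parameter in
#'   interval 0), `"worst"` (every parameter in its lowest-PS interval),
#'   `"mixed"` (alternating), or `"random"` (interval drawn uniformly per
#'   parameter).
#' @param n_fish Number of fish sampled for per-fish parameters (1..10).
#' @param missing_fraction Probability in `[0, 1)` that a parameter is
#'   reported `NA`.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, modules = NULL,
                         profile = c("optimal", "mixed", "worst", "random"),
                         n_fish = 1L, missing_fraction = 0) {
  profile <- match.arg(profile)
  stopifnot(n_fish >= 1L, n_fish <= 10L,
            missing_fraction >= 0, missing_fraction < 1)
  structure(list(seed = as.integer(seed), modules = modules,
                 profile = profile, n_fish = as.integer(n_fish),
                 missing_fraction = missing_fraction),
            class = "fixture_spec")
}

draw_in_interval <- function(iv_row, all_iv) {
  lo <- iv_row$lower; hi <- iv_row$upper
  widths <- all_iv$upper - all_iv$lower
  w <- if (any(is.finite(widths))) max(widths[is.finite(widths)]) else 1
  if (!is.finite(lo)) lo <- hi - w
  if (!is.finite(hi)) hi <- lo + w
  stats::runif(1L, lo, hi)
}

#' Generate a synthetic assessment from a configuration
#'
#' Draws one measurement per selected parameter (or one per fish for
#' per-fish parameters).  Numeric values are drawn uniformly within the
#' chosen interval's bounds (infinite outer bounds are clipped to the
#' parameter's largest finite interval width), so resolving the drawn
#' value returns the drawn interval.  Output is deterministic in
#' `spec$seed`; the caller's random-number state is left untouched.
#'
#' @param cfg A `welfare_config`.
#' @param spec A [fixture_spec()].
#' @return A `welfare_assessment` that validates against `cfg`.
#' @export
#' @examples
#' a <- generate_assessment(default_model_config(),
#'                          fixture_spec(1, profile = "random"))
generate_assessment <- function(cfg, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  mods <- spec$modules %||% cfg$modules$id
  params <- Filter(function(p) p$module %in% mods, cfg$parameters)
  recs <- list()
  for (p in params) {
    iv <- p$intervals[order(p$intervals$index), , drop = FALSE]
    if (stats::runif(1L) < spec$missing_fraction) {
      recs[[length(recs) + 1L]] <- data.frame(
        parameter_id = p$id, value = NA_character_,
        fish_index = NA_integer_, unit = p$unit, stringsAsFactors = FALSE)
      next
    }
    n <- if (p$per_fish) spec$n_fish else 1L
    for (fish in seq_len(n)) {
      row <- switch(spec$profile,
        optimal = iv[1L, , drop = FALSE],
        worst = iv[max(which(iv$PS == min(iv$PS))), , drop = FALSE],
        mixed = iv[1L + (length(recs) + fish) %% nrow(iv), , drop = FALSE],
        random = iv[sample.int(nrow(iv), 1L), , drop = FALSE])
      value <- if (p$kind == "numeric") {
        format(draw_in_interval(row, iv), digits = 15)
      } else row$label
      recs[[length(recs) + 1L]] <- data.frame(
        parameter_id = p$id, value = value,
        fish_index = if (p$per_fish) fish else NA_integer_,
        unit = p$unit, stringsAsFactors = FALSE)
    }
  }
  assessment(do.call(rbind, recs), location = "indoor", system = "RAS",
             species = "synthetic", purpose = "testing",
             timestamp = "1970-01-01",
             farm_id = paste0("synthetic-", spec$seed))
}
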