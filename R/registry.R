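# Scoring registry: modules, parameters, intervals and their weights.
#
# A model configuration holds five assessment modules (farm management M,
# water quality W, fish group behaviour FG, fish external appearance FE,
# fish internal appearance FI), and for every parameter an ordered list of
# intervals.  Each interval carries a parameter score PS in [-1, 0]
# (0 = no or positive influence on welfare, -1 = negative influence) and a
# score weight SW in 1..5 (stressor severity).  Each parameter carries a
# parameter weight PW in 1..5 (relative importance within its module).
# Interval index 0 is always the optimal interval with PS = 0 and SW = 1;
# indices enumerate intervals in order of increasing severity.

MODULE_IDS <- c("M", "W", "FG", "FE", "FI")

#' Construct a module definition
#'
#' @param id Module identifier, one of `"M"`, `"W"`, `"FG"`, `"FE"`, `"FI"`
#'   for the five standard modules; other identifiers are allowed for
#'   custom configurations.
#' @param name Human-readable module name.
#' @param SWE Score weight exponent (non-negative). The default grading
#'   model uses 1.7 for W, FG, FE and FI and 0 for M, where interval
#'   severity acts on welfare only indirectly.
#' @param PWE Parameter weight exponent (non-negative), 1.7 by default.
#'
#' @return A list of class `welfare_module`.
#' @export
#' @examples
#' module_def("W", "water quality")
module_def <- function(id, name = id, SWE = if (identical(id, "M")) 0 else 1.7,
                       PWE = 1.7) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(SWE) || length(SWE) != 1L || is.na(SWE) || SWE < 0)
    stop("module '", id, "': SWE must be a single non-negative number")
  if (!is.numeric(PWE) || length(PWE) != 1L || is.na(PWE) || PWE < 0)
    stop("module '", id, "': PWE must be a single non-negative number")
  structure(list(id = id, name = name, SWE = as.numeric(SWE),
                 PWE = as.numeric(PWE)),
            class = "welfare_module")
}

#' Construct a parameter interval table
#'
#' Builds the interval table of a parameter from parallel vectors.  Numeric
#' intervals are half-open `[lower, upper)` (lower-inclusive) so that a
#' measurement falling exactly on a printed threshold such as 16 in
#' "10-16 degC" is assigned deterministically; open outer ranges use
#' `-Inf`/`Inf` sentinels.  Ordinal intervals are identified by `label`
#' and matched by index or exact label.
#'
#' @param index Integer severity indices starting at 0 (the optimal
#'   interval, which must have `PS = 0` and `SW = 1`).
#' @param PS Parameter scores in `[-1, 0]`, non-increasing with `index`.
#' @param SW Integer score weights in 1..5, non-decreasing with `index`.
#' @param lower,upper Numeric bounds for numeric intervals (`NA` for
#'   ordinal intervals).
#' @param label Ordinal labels (`NA` for numeric intervals).
#'
#' @return A `data.frame` with one row per interval, ordered by `index`.
#' @export
interval_table <- function(index, PS, SW, lower = NA_real_, upper = NA_real_,
                           label = NA_character_) {
  n <- length(index)
  df <- data.frame(index = as.integer(index),
                   lower = rep_len(as.numeric(lower), n),
                   upper = rep_len(as.numeric(upper), n),
                   label = rep_len(as.character(label), n),
                   PS = as.numeric(PS),
                   SW = as.numeric(SW),
                   stringsAsFactors = FALSE)
  df[order(df$index), , drop = FALSE]
}

#' Construct a parameter definition
#'
#' @param id Stable parameter slug, unique within a configuration.
#' @param name Human-readable name.
#' @param module Identifier of the module the parameter belongs to.
#' @param intervals Interval table, see [interval_table()].
#' @param kind `"numeric"` or `"ordinal"`.
#' @param unit Measurement unit (empty string for ordinal parameters).
#' @param PW Integer parameter weight in 1..5.  Defaults to 3, the
#'   recommended weight for parameters without evidence of a lower or
#'   higher relative importance.
#' @param per_fish Is the parameter sampled on individual fish (external /
#'   internal appearance)?  Per-fish replicates are averaged before
#'   grading.
#' @param applicability Optional character tags (species, system,
#'   location) documenting when the parameter applies; a parameter that
#'   does not apply is reported as `NA` and excluded from the grade.
#'
#' @return A list of class `welfare_parameter`.
#' @export
parameter_def <- function(id, name, module, intervals,
                          kind = c("numeric", "ordinal"), unit = "",
                          PW = 3L, per_fish = FALSE,
                          applicability = character()) {
  kind <- match.arg(kind)
  structure(list(id = id, name = name, module = module, kind = kind,
                 unit = unit, PW = as.integer(PW),
                 per_fish = isTRUE(per_fish),
                 applicability = as.character(applicability),
                 intervals = intervals),
            class = "welfare_parameter")
}

#' Assemble a model configuration
#'
#' @param modules List of [module_def()] objects.
#' @param parameters List of [parameter_def()] objects.
#' @param provenance Free-text description of where intervals and weights
#'   come from.
#' @param schema_version Configuration schema version (currently 1).
#' @param validate Check all invariants (default `TRUE`).
#'
#' @return A list of class `welfare_config` with elements `modules`
#'   (a data frame) and `parameters` (a named list).
#' @export
model_config <- function(modules, parameters, provenance = "",
                         schema_version = 1L, validate = TRUE) {
  mod_df <- do.call(rbind, lapply(modules, function(m)
    data.frame(id = m$id, name = m$name, SWE = m$SWE, PWE = m$PWE,
               stringsAsFactors = FALSE)))
  names(parameters) <- vapply(parameters, `[[`, "", "id")
  cfg <- structure(list(schema_version = as.integer(schema_version),
                        provenance = provenance,
                        modules = mod_df,
                        parameters = parameters),
                   class = "welfare_config")
  if (validate) validate_config(cfg)
  cfg
}

#' Validate a model configuration
#'
#' Checks every registry invariant and reports all violations at once,
#' each naming the offending module or parameter and the rule broken:
#' unique module and parameter ids, non-negative exponents, known module
#' references, `PW` and `SW` in 1..5, `PS` in `[-1, 0]`, at least two
#' intervals per parameter, interval index 0 optimal (`PS = 0`, `SW = 1`),
#' `PS` non-increasing and `SW` non-decreasing with severity, and for
#' numeric parameters non-overlapping, gap-free half-open bounds.
#'
#' @param cfg A `welfare_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error listing every
#'   violation.
#' @export
validate_config <- function(cfg) {
  problems <- character()
  note <- function(...) problems <<- c(problems, paste0(...))

  if (!inherits(cfg, "welfare_config")) stop("not a welfare_config object")
  mods <- cfg$modules
  if (is.null(mods) || nrow(mods) == 0L) note("config: no modules defined")
  if (anyDuplicated(mods$id)) note("config: duplicate module id '",
                                   mods$id[duplicated(mods$id)][1L], "'")
  for (i in seq_len(nrow(mods))) {
    if (is.na(mods$SWE[i]) || mods$SWE[i] < 0)
      note("module '", mods$id[i], "': SWE must be >= 0")
    if (is.na(mods$PWE[i]) || mods$PWE[i] < 0)
      note("module '", mods$id[i], "': PWE must be >= 0")
  }

  ids <- names(cfg$parameters)
  if (anyDuplicated(ids)) note("config: duplicate parameter id '",
                               ids[duplicated(ids)][1L], "'")
  for (p in cfg$parameters) {
    where <- paste0("parameter '", p$id, "'")
    if (!p$module %in% mods$id)
      note(where, ": unknown module reference '", p$module, "'")
    if (is.na(p$PW) || p$PW < 1L || p$PW > 5L || p$PW != as.integer(p$PW))
      note(where, ": PW must be an integer in 1..5 (got ", p$PW, ")")
    iv <- p$intervals
    if (is.null(iv) || nrow(iv) < 2L) {
      note(where, ": needs at least 2 intervals")
      next
    }
    if (anyDuplicated(iv$index))
      note(where, ": duplicate interval index")
    if (min(iv$index) != 0L)
      note(where, ": interval indices must start at 0")
    iv <- iv[order(iv$index), , drop = FALSE]
    if (any(is.na(iv$PS)) || any(iv$PS < -1) || any(iv$PS > 0))
      note(where, ": PS out of range [-1, 0]")
    if (any(is.na(iv$SW)) || any(iv$SW < 1) || any(iv$SW > 5) ||
        any(iv$SW != round(iv$SW)))
      note(where, ": SW must be an integer in 1..5")
    else {
      if (iv$PS[1L] != 0) note(where, ": interval 0 must have PS = 0")
      if (iv$SW[1L] != 1) note(where, ": interval 0 must have SW = 1")
      if (is.unsorted(rev(iv$PS))) # PS non-increasing with severity
        note(where, ": PS must be non-increasing with interval index")
      if (is.unsorted(iv$SW))
        note(where, ": SW must be non-decreasing with interval index")
    }
    if (p$kind == "numeric") {
      if (any(is.na(iv$lower)) || any(is.na(iv$upper)))
        note(where, ": numeric intervals need lower and upper bounds")
      else {
        if (any(iv$lower >= iv$upper))
          note(where, ": interval bounds must satisfy lower < upper")
        bo <- iv[order(iv$lower), , drop = FALSE]
        if (nrow(bo) > 1L) {
          gaps <- bo$lower[-1L] - bo$upper[-nrow(bo)]
          if (any(gaps > 0))
            note(where, ": numeric intervals leave a gap in coverage")
          if (any(gaps < 0))
            note(where, ": numeric intervals overlap")
        }
      }
    } else {
      if (any(is.na(iv$label)) || any(!nzchar(iv$label)))
        note(where, ": ordinal intervals need labels")
      else if (anyDuplicated(iv$label))
        note(where, ": duplicate ordinal label")
    }
  }

  if (length(problems))
    stop("invalid model configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  invisible(cfg)
}

#' @export
print.welfare_config <- function(x, ...) {
  cat("<welfare_config> schema v", x$schema_version, "\n", sep = "")
  tab <- table(factor(vapply(x$parameters, `[[`, "", "module"),
                      levels = x$modules$id))
  cat(length(x$parameters), "parameters in", nrow(x$modules), "modules:\n")
  for (m in x$modules$id)
    cat(sprintf("  %-3s %-26s %3d parameters (SWE=%.1f, PWE=%.1f)\n", m,
                x$modules$name[x$modules$id == m], tab[[m]],
                x$modules$SWE[x$modules$id == m],
                x$modules$PWE[x$modules$id == m]))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

config_to_list <- function(cfg) {
  list(
    schema_version = cfg$schema_version,
    provenance = cfg$provenance,
    modules = lapply(seq_len(nrow(cfg$modules)), function(i)
      as.list(cfg$modules[i, , drop = FALSE])),
    parameters = unname(lapply(cfg$parameters, function(p) {
      iv <- p$intervals
      list(id = p$id, name = p$name, module = p$module, kind = p$kind,
           unit = p$unit, PW = p$PW, per_fish = p$per_fish,
           applicability = as.list(p$applicability),
           intervals = lapply(seq_len(nrow(iv)), function(j) {
             row <- list(index = iv$index[j], PS = iv$PS[j], SW = iv$SW[j])
             if (p$kind == "numeric") {
               row$lower <- iv$lower[j]; row$upper <- iv$upper[j]
             } else row$label <- iv$label[j]
             row
           }))
    }))
  )
}

config_from_list <- function(x, validate = TRUE) {
  num1 <- function(v) {
    if (is.null(v)) return(NA_real_)
    if (is.character(v)) { # JSON has no Inf literal; accept strings
      v <- switch(v, "Inf" = Inf, ".inf" = Inf, "-Inf" = -Inf,
                  "-.inf" = -Inf, suppressWarnings(as.numeric(v)))
    }
    as.numeric(v)
  }
  modules <- lapply(x$modules, function(m)
    module_def(m$id, m$name %||% m$id, SWE = num1(m$SWE), PWE = num1(m$PWE)))
  parameters <- lapply(x$parameters, function(p) {
    iv <- p$intervals
    tab <- interval_table(
      index = vapply(iv, function(r) as.integer(r$index), 0L),
      PS = vapply(iv, function(r) num1(r$PS), 0),
      SW = vapply(iv, function(r) num1(r$SW), 0),
      lower = vapply(iv, function(r) num1(r$lower), 0),
      upper = vapply(iv, function(r) num1(r$upper), 0),
      label = vapply(iv, function(r) as.character(r$label %||% NA_character_), ""))
    parameter_def(p$id, p$name %||% p$id, p$module, tab,
                  kind = p$kind, unit = p$unit %||% "",
                  PW = p$PW %||% 3L, per_fish = isTRUE(p$per_fish),
                  applicability = unlist(p$applicability) %||% character())
  })
  model_config(modules, parameters,
               provenance = x$provenance %||% "",
               schema_version = x$schema_version %||% 1L,
               validate = validate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("yaml", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) "yaml"
  else if (ext == "json") "json"
  else stop("cannot infer format from '", path, "'; pass format=")
}

#' Load a model configuration from YAML or JSON
#'
#' @param source Path to a configuration file, or a single string of
#'   YAML/JSON text.
#' @param format `"yaml"` or `"json"`; inferred from the file extension
#'   when `NULL`.
#' @param validate Check all registry invariants after parsing.
#'
#' @return A validated `welfare_config`.
#' @seealso [write_model_config()], [default_model_config()]
#' @export
#' @examples
#' cfg <- default_model_config()
#' length(cfg$parameters)
load_model_config <- function(source, format = NULL, validate = TRUE) {
  is_file <- length(source) == 1L && !grepl("\n", source) &&
    file.exists(source)
  format <- guess_format(if (is_file) source else "", format)
  x <- if (format == "yaml") {
    if (is_file) yaml::read_yaml(source) else yaml::yaml.load(source)
  } else {
    jsonlite::fromJSON(source, simplifyVector = FALSE)
  }
  config_from_list(x, validate = validate)
}

#' Write a model configuration to YAML or JSON
#'
#' The written file reloads to a structurally identical configuration
#' (round-trip identity up to field ordering).
#'
#' @param cfg A `welfare_config`.
#' @param path Output path.
#' @param format `"yaml"` or `"json"`; inferred from the extension when
#'   `NULL`.  Infinite numeric bounds are serialized as `.inf` in YAML and
#'   as the strings `"Inf"`/`"-Inf"` in JSON.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(cfg, path, format = NULL) {
  format <- guess_format(path, format)
  x <- config_to_list(cfg)
  if (format == "yaml") {
    yaml::write_yaml(x, path, precision = 12L)
  } else {
    # JSON cannot carry bare infinities; jsonlite writes them as the
    # strings "Inf"/"-Inf", which config_from_list() converts back
    txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                            na = "string", pretty = TRUE)
    writeLines(txt, path)
  }
  invisible(path)
}

#' The shipped default model configuration
#'
#' Reads the packaged default scoring registry: 80 parameters across the
#' five modules (18 farm-management, 14 water-quality, 20 group-behaviour,
#' 18 external-appearance, 10 internal-appearance parameters), with
#' exponents SWE = PWE = 1.7 (SWE = 0 for module M).  Interval boundaries
#' follow common husbandry guidance for freshwater salmonid and percid
#' grow-out; parameter scores are spaced linearly from 0 to -1 across each
#' parameter's intervals and all parameter weights default to 3.  See the
#' configuration's `provenance` field and the package vignette for what is
#' and is not literature-calibrated in this registry.
#'
#' @return A validated `welfare_config`.
#' @export
default_model_config <- function() {
  path <- system.file("extdata", "default_config.yaml",
                      package = "fishwelfare", mustWork = TRUE)
  load_model_config(path)
}

# ---- interval resolution ---------------------------------------------------

#' Resolve a measured value to its parameter interval
#'
#' Numeric values are matched under the half-open `[lower, upper)`
#' convention, so a value equal to an interval's lower bound belongs to
#' that interval.  Ordinal values match by interval index (numeric input)
#' or by exact label (character input).
#'
#' @param param A `welfare_parameter`.
#' @param value A finite numeric value in the parameter's unit, or for
#'   ordinal parameters an interval index or label.
#' @return One row of the parameter's interval table.  A value outside
#'   every interval or an unknown label is an error (a config/measurement
#'   mismatch), never a silent `NA`.
#' @export
#' @examples
#' p <- parameter_def("w_temperature", "Temperature", "W",
#'   interval_table(index = 0:1, PS = c(0, -1), SW = c(1, 3),
#'                  lower = c(10, 16), upper = c(16, 40)))
#' resolve_interval(p, 12)$index  # 0
resolve_interval <- function(param, value) {
  iv <- param$intervals
  if (param$kind == "numeric") {
    v <- suppressWarnings(as.numeric(value))
    if (length(v) != 1L || is.na(v) || !is.finite(v))
      stop("parameter '", param$id, "': numeric value required, got '",
           value, "'")
    hit <- which(iv$lower <= v & v < iv$upper)
    if (length(hit) == 0L)
      stop("parameter '", param$id, "': value ", v,
           " lies outside all configured intervals")
  } else {
    if (is.character(value) &&
        is.na(suppressWarnings(as.numeric(value)))) {
      hit <- which(iv$label == value)
      if (length(hit) == 0L)
        stop("parameter '", param$id, "': unknown ordinal label '",
             value, "'")
    } else {
      idx <- suppressWarnings(as.integer(as.numeric(value)))
      hit <- which(iv$index == idx)
      if (length(hit) == 0L)
        stop("parameter '", param$id, "': no interval with index ",
             value)
    }
  }
  iv[hit[1L], , drop = FALSE]
}

# ---- regulatory overrides --------------------------------------------------

#' Construct a regulatory override
#'
#' Local laws or label standards may police individual parameters
#' (e.g. stocking density, dissolved oxygen, ammonia); an override swaps a
#' parameter's interval table for a jurisdiction-specific one without
#' touching the rest of the configuration.
#'
#' @param parameter_id Target parameter.
#' @param intervals Replacement interval table ([interval_table()]); must
#'   satisfy every interval invariant.
#' @param jurisdiction Label for the legal source, e.g. `"CH"`.
#' @param rationale Free-text reason.
#' @return A list of class `welfare_override`.
#' @export
regulatory_override <- function(parameter_id, intervals, jurisdiction,
                                rationale = "") {
  structure(list(parameter_id = parameter_id, intervals = intervals,
                 jurisdiction = jurisdiction, rationale = rationale),
            class = "welfare_override")
}

#' Apply regulatory overrides to a configuration
#'
#' Returns a new configuration with the targeted parameters' intervals
#' replaced; the input configuration is unchanged and the result's
#' provenance records each jurisdiction.  Applying the same override twice
#' is idempotent.
#'
#' @param cfg A `welfare_config`.
#' @param overrides List of [regulatory_override()] objects (an empty list
#'   returns `cfg` unchanged).
#' @return A validated `welfare_config`.
#' @export
apply_overrides <- function(cfg, overrides) {
  if (length(overrides) == 0L) return(cfg)
  for (ov in overrides) {
    if (!ov$parameter_id %in% names(cfg$parameters))
      stop("override targets unknown parameter '", ov$parameter_id, "'")
    cfg$parameters[[ov$parameter_id]]$intervals <- ov$intervals
    stamp <- paste0("override[", ov$jurisdiction, "]: ", ov$parameter_id)
    if (!grepl(stamp, cfg$provenance, fixed = TRUE))
      cfg$provenance <- paste0(cfg$provenance,
                               if (nzchar(cfg$provenance)) "; ", stamp)
  }
  validate_config(cfg)
  cfg
}
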