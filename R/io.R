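# Assessment I/O: reading and writing assessments, grade reports,
# comparisons between visits, and the command-line entry point.
#
# Assessment CSV dialect: comma-separated UTF-8 with a header row and
# columns parameter_id, value, fish_index, unit (the last two optional);
# the literal string "NA" marks a value that is missing or not applicable.
# The JSON form wraps the same measurement records together with the farm
# metadata.  Reports embed a checksum of the configuration so that two
# assessments graded under different configurations are refused when
# compared, never silently merged.

#' Construct an assessment
#'
#' One farm visit: metadata plus a table of per-parameter measurements
#' (optionally one row per sampled fish for per-fish parameters).
#'
#' @param measurements Data frame with columns `parameter_id`, `value`
#'   and optional `fish_index`, `unit`.  Values are kept as character;
#'   ordinal values may be interval indices or labels, and `"NA"` marks a
#'   missing / not-applicable value.
#' @param location `"indoor"` or `"outdoor"`.
#' @param system Husbandry system, e.g. `"RAS"` (recirculating) or
#'   `"FTS"` (flow-through).
#' @param species Species label, e.g. `"rainbow trout"`.
#' @param purpose Production purpose, e.g. `"grow-out"`.
#' @param timestamp Visit time as text (kept verbatim so that repeated
#'   runs are byte-identical).
#' @param farm_id Optional farm label.
#' @return A list of class `welfare_assessment`.
#' @export
assessment <- function(measurements, location = NA_character_,
                       system = NA_character_, species = NA_character_,
                       purpose = NA_character_, timestamp = NA_character_,
                       farm_id = NA_character_) {
  measurements <- normalize_measurements(measurements)
  structure(list(
    metadata = list(farm_id = farm_id, location = location,
                    system = system, species = species, purpose = purpose,
                    timestamp = timestamp),
    measurements = measurements),
    class = "welfare_assessment")
}

normalize_measurements <- function(df) {
  if (!all(c("parameter_id", "value") %in% names(df)))
    stop("measurements need columns parameter_id and value")
  if (!"fish_index" %in% names(df)) df$fish_index <- NA_integer_
  if (!"unit" %in% names(df)) df$unit <- NA_character_
  df <- df[c("parameter_id", "value", "fish_index", "unit")]
  df$parameter_id <- as.character(df$parameter_id)
  df$value <- as.character(df$value)
  df$value[df$value %in% c("NA", "")] <- NA_character_
  df$fish_index <- suppressWarnings(as.integer(df$fish_index))
  df$unit <- as.character(df$unit)
  df$unit[!is.na(df$unit) & !nzchar(df$unit)] <- NA_character_
  key <- paste(df$parameter_id, df$fish_index)
  if (anyDuplicated(key))
    stop("duplicate measurement for parameter '",
         df$parameter_id[duplicated(key)][1L], "' (same fish_index)")
  df
}

#' @export
print.welfare_assessment <- function(x, ...) {
  md <- x$metadata
  cat("<welfare_assessment>",
      if (!is.na(md$farm_id)) paste0("farm ", md$farm_id), md$location,
      md$system, md$species, "-", nrow(x$measurements), "measurements\n")
  invisible(x)
}

#' Read an assessment from CSV or JSON
#'
#' @param path Input file.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   `NULL`.
#' @param cfg Optional `welfare_config`; when given, every parameter id
#'   must exist in the configuration and any non-empty `unit` entries must
#'   match the configured units.
#' @param ... For CSV input, metadata fields passed to [assessment()]
#'   (`location`, `system`, ...); JSON input carries its own metadata.
#' @return A `welfare_assessment`.
#' @export
read_assessment <- function(path, format = NULL, cfg = NULL, ...) {
  format <- if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "csv") "csv" else if (ext == "json") "json"
    else stop("cannot infer format from '", path, "'; pass format=")
  } else match.arg(format, c("csv", "json"))
  a <- if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
    assessment(df, ...)
  } else {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    ms <- x$measurements
    df <- data.frame(
      parameter_id = vapply(ms, function(m) as.character(m$parameter_id), ""),
      value = vapply(ms, function(m)
        if (is.null(m$value)) NA_character_ else as.character(m$value), ""),
      fish_index = vapply(ms, function(m)
        if (is.null(m$fish_index)) NA_integer_ else as.integer(m$fish_index),
        0L),
      unit = vapply(ms, function(m)
        if (is.null(m$unit)) NA_character_ else as.character(m$unit), ""),
      stringsAsFactors = FALSE)
    md <- x$metadata
    assessment(df, location = md$location %||% NA_character_,
               system = md$system %||% NA_character_,
               species = md$species %||% NA_character_,
               purpose = md$purpose %||% NA_character_,
               timestamp = md$timestamp %||% NA_character_,
               farm_id = md$farm_id %||% NA_character_)
  }
  if (!is.null(cfg)) validate_assessment(a, cfg)
  a
}

#' Validate an assessment against a configuration
#'
#' @param a A `welfare_assessment`.
#' @param cfg A `welfare_config`.
#' @return `a`, invisibly; errors name unknown parameters, malformed
#'   numeric values and unit mismatches.
#' @export
validate_assessment <- function(a, cfg) {
  df <- a$measurements
  unknown <- setdiff(df$parameter_id, names(cfg$parameters))
  if (length(unknown))
    stop("unknown parameter id(s): ", paste(unique(unknown), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    p <- cfg$parameters[[df$parameter_id[i]]]
    if (!is.na(df$unit[i]) && nzchar(df$unit[i]) && nzchar(p$unit) &&
        !identical(df$unit[i], p$unit))
      stop("parameter '", p$id, "': unit mismatch ('", df$unit[i],
           "' in file, '", p$unit, "' in config)")
    v <- df$value[i]
    if (is.na(v)) next
    if (p$kind == "numeric" && is.na(suppressWarnings(as.numeric(v))))
      stop("parameter '", p$id, "': malformed numeric value '", v, "'")
    resolve_interval(p, v)  # errors on out-of-range / unknown label
    if (!is.na(df$fish_index[i]) && !p$per_fish)
      stop("parameter '", p$id, "': fish_index given but parameter is ",
           "not sampled per fish")
  }
  invisible(a)
}

#' Write an assessment to CSV or JSON
#'
#' @param a A `welfare_assessment`.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   `NULL`.  CSV keeps the measurement table only (metadata travels in
#'   JSON or alongside); a write/read round trip restores the structure.
#' @return `path`, invisibly.
#' @export
write_assessment <- function(a, path, format = NULL) {
  format <- if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "csv") "csv" else "json"
  } else match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- a$measurements
    df$value[is.na(df$value)] <- "NA"
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    x <- list(metadata = a$metadata,
              measurements = lapply(seq_len(nrow(a$measurements)),
                                    function(i)
                as.list(a$measurements[i, , drop = FALSE])))
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null", na = "null"),
               path)
  }
  invisible(path)
}

#' Checksum of a model configuration
#'
#' Deterministic 31-polynomial hash over the canonical JSON serialization;
#' embedded in reports so that comparisons across differing
#' configurations can be refused.
#'
#' @param cfg A `welfare_config`.
#' @return Checksum as a hexadecimal string.
#' @export
config_checksum <- function(cfg) {
  txt <- jsonlite::toJSON(config_to_list(cfg), auto_unbox = TRUE,
                          digits = NA, na = "string")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build a serializable assessment report
#'
#' @param grades A `welfare_grades` result from [assess()].
#' @param cfg The `welfare_config` used.
#' @return A list of class `assessment_report` with farm metadata, config
#'   provenance and checksum, engine version, per-module grades with
#'   per-parameter breakdowns, and any warnings.  Serializes to JSON and
#'   back losslessly via [write_report()] / [read_report()].
#' @export
assessment_report <- function(grades, cfg) {
  results <- lapply(grades, function(r) {
    list(module_id = r$module_id, grade = r$grade,
         grade_rounded = r$grade_rounded, category = r$category,
         n_missing = r$n_missing,
         parameters = lapply(seq_len(nrow(r$scored)), function(i)
           as.list(r$scored[i, , drop = FALSE])))
  })
  structure(list(
    metadata = attr(grades, "metadata"),
    config_provenance = cfg$provenance,
    config_checksum = config_checksum(cfg),
    engine_version = as.character(utils::packageVersion("fishwelfare")),
    results = results,
    warnings = as.list(attr(grades, "warnings") %||% character())),
    class = "assessment_report")
}

#' Write / read an assessment report (JSON)
#'
#' @param report An `assessment_report`.
#' @param path File path.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the `assessment_report`.
#' @export
write_report <- function(report, path) {
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA, null = "null",
                              na = "null"),
             path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  x$warnings <- x$warnings %||% list()
  structure(x, class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  md <- x$metadata
  cat("Assessment report",
      if (!is.null(md$farm_id) && !is.na(md$farm_id))
        paste0("(farm ", md$farm_id, ")"), "\n")
  cat(sprintf("  %-3s %-7s %-10s %s\n", "mod", "grade", "category",
              "scored/missing"))
  for (r in x$results)
    cat(sprintf("  %-3s %-7.2f %-10s %d/%d\n", r$module_id,
                r$grade_rounded, r$category, length(r$parameters),
                r$n_missing))
  invisible(x)
}

#' Compare two assessment reports
#'
#' Computes per-module grade deltas (later minus earlier) and lists the
#' parameters whose effective score changed between the two visits.  Both
#' reports must have been graded under the same configuration (checked by
#' checksum).
#'
#' @param earlier,later `assessment_report` objects.
#' @return A list of class `comparison_report` with a `deltas` data frame
#'   (`module_id`, `earlier`, `later`, `delta`) and a `changed_parameters`
#'   data frame.
#' @export
compare_assessments <- function(earlier, later) {
  if (!identical(earlier$config_checksum, later$config_checksum))
    stop("reports were graded under different configurations ",
         "(checksum mismatch); comparison refused")
  mods <- union(vapply(earlier$results, `[[`, "", "module_id"),
                vapply(later$results, `[[`, "", "module_id"))
  grade_of <- function(rep, m) {
    for (r in rep$results) if (identical(r$module_id, m)) return(r$grade)
    NA_real_
  }
  deltas <- data.frame(
    module_id = mods,
    earlier = vapply(mods, function(m) grade_of(earlier, m), 0),
    later = vapply(mods, function(m) grade_of(later, m), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  deltas$delta <- deltas$later - deltas$earlier

  ps_map <- function(rep) {
    out <- list()
    for (r in rep$results) for (p in r$parameters)
      out[[p$parameter_id]] <- p$effective_PS
    out
  }
  e <- ps_map(earlier); l <- ps_map(later)
  ids <- union(names(e), names(l))
  changed <- ids[vapply(ids, function(id)
    !isTRUE(all.equal(e[[id]] %||% NA_real_, l[[id]] %||% NA_real_)),
    TRUE)]
  structure(list(
    earlier_farm = earlier$metadata$farm_id,
    later_farm = later$metadata$farm_id,
    deltas = deltas,
    changed_parameters = changed),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison (later - earlier):\n")
  for (i in seq_len(nrow(x$deltas)))
    cat(sprintf("  %-3s %+0.2f (%.2f -> %.2f)\n", x$deltas$module_id[i],
                x$deltas$delta[i], x$deltas$earlier[i], x$deltas$later[i]))
  if (length(x$changed_parameters))
    cat("changed parameters:",
        paste(x$changed_parameters, collapse = ", "), "\n")
  invisible(x)
}
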