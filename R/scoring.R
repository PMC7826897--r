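# Scoring engine: from measurements to module grades.
#
# Every measured parameter resolves to an interval carrying a parameter
# score PS in [-1, 0] and a score weight SW in 1..5; the parameter itself
# carries a parameter weight PW in 1..5.  A module's grade is the
# exponent-weighted mean of its parameter scores, offset by 1:
#
#   MG = 1 + sum_i( PS_i * SW_i^SWE * PW_i^PWE ) /
#            sum_i(        SW_i^SWE * PW_i^PWE )
#
# over the measured (non-missing) parameters i of the module.  Writing the
# normalisation with the same exponent-weighted terms as the numerator
# makes MG a weighted mean of (1 + PS): MG is guaranteed to lie in [0, 1],
# equals 1 exactly when every score is 0 and 0 exactly when every score is
# -1, and is unchanged when parameters are duplicated or when unmeasured
# parameters are dropped.  Module M uses SWE = 0, which makes its grade
# independent of the score weights.  Grades are categorised as
# critical [0, 0.25), poor [0.25, 0.5), acceptable [0.5, 0.75) or
# good [0.75, 1].

CATEGORY_LEVELS <- c("critical", "poor", "acceptable", "good")

scored_row <- function(parameter_id, module, PS, SW, PW, n_fish = 1L) {
  data.frame(parameter_id = parameter_id, module = module,
             effective_PS = PS, effective_SW = SW, PW = PW,
             n_fish_averaged = as.integer(n_fish),
             stringsAsFactors = FALSE)
}

#' Score one measurement against the configuration
#'
#' Resolves the measured value to its interval and attaches the interval's
#' PS and SW together with the parameter's PW.  A missing value (`NA`)
#' yields `NULL`, the missing-marker: the parameter is excluded from both
#' the numerator and the normalisation of the module grade, so grades stay
#' valid when only a subset of parameters was measured.
#'
#' @param value Measured value (numeric, ordinal index or label, or `NA`).
#' @param param A `welfare_parameter` from the configuration.
#' @return A one-row scored data frame, or `NULL` for a missing value.
#' @export
score_measurement <- function(value, param) {
  if (length(value) != 1L || is.na(value) ||
      (is.character(value) && value %in% c("NA", "")))
    return(NULL)
  iv <- resolve_interval(param, value)
  scored_row(param$id, param$module, iv$PS, iv$SW, param$PW)
}

#' Average per-fish scores for one parameter
#'
#' External- and internal-appearance parameters are sampled on individual
#' fish; their per-fish scores are averaged before grading.  The effective
#' PS and SW are the arithmetic means over fish (so effective weights may
#' be non-integer).  Fewer than three fish give unreliable estimates and
#' trigger a warning; more than ten mainly prolong the assessment.
#'
#' @param scored Scored data frame with one row per fish, all rows sharing
#'   one `parameter_id`.
#' @return A one-row scored data frame with `n_fish_averaged` set.
#' @export
average_fish_scores <- function(scored) {
  if (is.null(scored) || nrow(scored) == 0L)
    stop("average_fish_scores: empty input")
  if (length(unique(scored$parameter_id)) != 1L)
    stop("average_fish_scores: rows must share one parameter_id")
  n <- nrow(scored)
  if (n < 3L)
    warning("parameter '", scored$parameter_id[1L], "': only ", n,
            " fish sampled; fewer than three fish yield unreliable results")
  scored_row(scored$parameter_id[1L], scored$module[1L],
             mean(scored$effective_PS), mean(scored$effective_SW),
             scored$PW[1L], n_fish = n)
}

#' Compute a module grade
#'
#' Evaluates the exponent-weighted grading equation over the scored
#' (non-missing) parameters of one module.
#'
#' @param scored Scored data frame (rows for this module only).
#' @param mod One row of a configuration's `modules` data frame, or a
#'   [module_def()]; supplies `SWE` and `PWE`.
#' @param n_missing Count of parameters excluded as not measured /
#'   not applicable (carried through for reporting).
#' @return A list of class `module_grade_result` with the unrounded
#'   `grade` in `[0, 1]`, the reported `grade_rounded` (two decimals, half
#'   away from zero), the `category` (computed from the unrounded grade),
#'   and the per-parameter breakdown.
#' @export
module_grade <- function(scored, mod, n_missing = 0L) {
  if (is.null(scored) || nrow(scored) == 0L)
    stop("module '", mod$id, "': no measured parameters to grade")
  w <- scored$effective_SW^mod$SWE * scored$PW^mod$PWE
  grade <- 1 + sum(scored$effective_PS * w) / sum(w)
  grade <- min(max(grade, 0), 1)  # clamp floating-point dust only
  structure(list(module_id = mod$id, grade = grade,
                 grade_rounded = round_half_up(grade, 2),
                 category = categorize(grade),
                 scored = scored, n_missing = as.integer(n_missing)),
            class = "module_grade_result")
}

#' @export
print.module_grade_result <- function(x, ...) {
  cat(sprintf("module %-3s grade %.2f (%s), %d parameters scored, %d missing\n",
              x$module_id, x$grade_rounded, x$category, nrow(x$scored),
              x$n_missing))
  invisible(x)
}

#' Semantic welfare category of a grade
#'
#' `[0, 0.25)` critical (welfare severely compromised, short- and
#' long-term impairments expected); `[0.25, 0.5)` poor (long-term
#' impairments expected); `[0.5, 0.75)` acceptable (improvable);
#' `[0.75, 1]` good.
#'
#' @param grade Numeric grade(s) in `[0, 1]`.
#' @return Character vector of categories.
#' @export
#' @examples
#' categorize(c(0.31, 0.75, 1))
categorize <- function(grade) {
  if (any(!is.finite(grade)) || any(grade < 0) || any(grade > 1))
    stop("grade must lie in [0, 1]")
  CATEGORY_LEVELS[findInterval(grade, c(0, 0.25, 0.5, 0.75, 1),
                               rightmost.closed = TRUE)]
}

#' Grade a farm assessment
#'
#' Scores every measurement against the configuration, averages per-fish
#' replicates, and grades each module independently.  Modules without any
#' measured parameter are omitted from the result (absence of evidence is
#' not good welfare) with a notice.
#'
#' @param assessment A `welfare_assessment` (see [assessment()] /
#'   [read_assessment()]).
#' @param cfg A `welfare_config`.
#' @return A list of class `welfare_grades`: one `module_grade_result`
#'   per module with data, named by module id, with the assessment
#'   metadata and any warnings attached as attributes.
#' @export
#' @examples
#' grades <- assess(load_farm_fixture(2), default_model_config())
#' grades$FI$grade_rounded  # 1
assess <- function(assessment, cfg) {
  meas <- assessment$measurements
  unknown <- setdiff(meas$parameter_id, names(cfg$parameters))
  if (length(unknown))
    stop("assessment contains parameters unknown to the configuration: ",
         paste(unique(unknown), collapse = ", "))
  warnings <- character()

  scored_list <- list()
  n_missing <- stats::setNames(integer(nrow(cfg$modules)), cfg$modules$id)
  for (pid in unique(meas$parameter_id)) {
    param <- cfg$parameters[[pid]]
    rows <- meas[meas$parameter_id == pid, , drop = FALSE]
    per_fish <- lapply(seq_len(nrow(rows)), function(i)
      score_measurement(rows$value[i], param))
    per_fish <- per_fish[!vapply(per_fish, is.null, TRUE)]
    if (length(per_fish) == 0L) {
      n_missing[[param$module]] <- n_missing[[param$module]] + 1L
      next
    }
    one <- if (length(per_fish) == 1L) per_fish[[1L]] else {
      if (!param$per_fish)
        stop("parameter '", pid,
             "' has replicate measurements but is not per-fish")
      n <- length(per_fish)
      if (n < 3L)
        warnings <- c(warnings, paste0(
          "parameter '", pid, "': only ", n, " fish sampled"))
      suppressWarnings(average_fish_scores(do.call(rbind, per_fish)))
    }
    scored_list[[pid]] <- one
  }
  scored <- do.call(rbind, scored_list)

  results <- list()
  for (i in seq_len(nrow(cfg$modules))) {
    mod <- cfg$modules[i, , drop = FALSE]
    sub <- scored[scored$module == mod$id, , drop = FALSE]
    if (is.null(sub) || nrow(sub) == 0L) {
      if (n_missing[[mod$id]] > 0L)
        message("module ", mod$id,
                ": no measured parameters; module omitted from results")
      next
    }
    results[[mod$id]] <- module_grade(sub, mod,
                                      n_missing = n_missing[[mod$id]])
  }
  if (length(results) == 0L)
    stop("assessment contains no measured parameters")
  structure(results, class = "welfare_grades",
            metadata = assessment$metadata, warnings = warnings)
}

#' @export
print.welfare_grades <- function(x, ...) {
  md <- attr(x, "metadata")
  if (!is.null(md) && length(md))
    cat("assessment:", paste(unlist(md), collapse = " / "), "\n")
  for (r in x) print(r)
  w <- attr(x, "warnings")
  if (length(w)) cat("warnings:\n ", paste(w, collapse = "\n  "), "\n")
  invisible(x)
}

#' Calibrate the weight exponents on boundary data sets
#'
#' The grading exponents were chosen so that scored data sets with a
#' clear, known welfare status fall into the intended category — a
#' multiclass classification with fixed decision boundaries and a
#' parametric feature transformation.  This harness reproduces that
#' procedure by grid search: both exponents are kept identical
#' (`SWE = PWE`), each candidate is applied to every boundary data set,
#' and the candidate minimising the number of misclassified categories
#' wins; ties break toward the smallest exponent.
#'
#' @param boundary_datasets List of `list(scored = <scored data frame>,
#'   target = <category>)` pairs.
#' @param grid Numeric vector of candidate exponent values.
#' @return A list with the winning `exponent`, its `misclassified` count,
#'   and the per-candidate `errors` table.
#' @export
calibrate_exponents <- function(boundary_datasets, grid) {
  if (length(boundary_datasets) == 0L || length(grid) == 0L)
    stop("calibrate_exponents: empty boundary datasets or grid")
  grid <- sort(unique(as.numeric(grid)))
  errs <- vapply(grid, function(e) {
    mod <- module_def("CAL", "calibration", SWE = e, PWE = e)
    sum(vapply(boundary_datasets, function(d) {
      g <- module_grade(d$scored, mod)
      g$category != d$target
    }, TRUE))
  }, 0L)
  best <- which.min(errs)  # ties -> smallest exponent (grid sorted)
  list(exponent = grid[best], misclassified = errs[best],
       errors = data.frame(exponent = grid, misclassified = errs))
}
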