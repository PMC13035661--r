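#' Pipeline configuration
#'
#' Bundles the tunable parameters of the measurement and evaluation
#' pipeline. Units are fixed (mm, mL, days) and never auto-converted.
#'
#' @param label_map Label codes (see [default_label_map()]).
#' @param step Centerline resampling step, mm.
#' @param end_guard Diameter-profile end guard, mm.
#' @param section_length Primary FL_Loc section length, mm.
#' @param section_sweep Optional extra section lengths, mm.
#' @param min_separation Candidate-position separation, mm.
#' @param plane_extent Diameter sampling plane extent, mm.
#' @param year_length Days per year for evolution markers.
#' @param ci_level Confidence level for AUC intervals.
#' @param seed Integer seed for any stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(label_map = default_label_map(), step = 1,
                       end_guard = 10, section_length = 30,
                       section_sweep = NULL, min_separation = 10,
                       plane_extent = 120, year_length = 365,
                       ci_level = 0.95, seed = 1L) {
  if (step <= 0 || section_length <= 0 || plane_extent <= 0 || year_length <= 0) {
    abort("all lengths must be positive")
  }
  if (ci_level <= 0 || ci_level >= 1) abort("ci_level must be in (0, 1)")
  structure(
    list(label_map = label_map, step = step, end_guard = end_guard,
         section_length = section_length, section_sweep = section_sweep,
         min_separation = min_separation, plane_extent = plane_extent,
         year_length = year_length, ci_level = ci_level,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Measure a batch of label volumes
#'
#' Runs the full morphometry pipeline on each NIfTI path: one output row
#' per scan with every measure (mm, mL). Per-scan failures are reported and
#' the run continues; failed scans are listed in the `failures` attribute.
#'
#' @param paths Character vector of NIfTI label-volume paths.
#' @param config A [run_config()].
#' @param out_csv Optional CSV path for the measurement table.
#' @return Tibble of measurements (attribute `failures`: named character
#'   vector of error messages for scans that could not be measured).
#' @export
run_measure <- function(paths, config = run_config(), out_csv = NULL) {
  rows <- list()
  failures <- character(0)
  for (p in paths) {
    res <- tryCatch({
      vol <- read_label_volume(p, label_map = config$label_map)
      m <- measure_aorta(vol, step = config$step, end_guard = config$end_guard,
                         section_length = config$section_length,
                         min_separation = config$min_separation,
                         sweep = config$section_sweep,
                         plane_extent = config$plane_extent)
      dplyr::bind_cols(tibble::tibble(scan = basename(p)), m)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[p] <- res
      warn(paste0("failed to measure ", p, ": ", res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble()
  attr(out, "failures") <- failures
  if (!is.null(out_csv) && nrow(out)) readr::write_csv(out, out_csv)
  out
}

#' Evaluate markers on a cohort table
#'
#' Data-frame-first front end to [evaluate_markers()]: accepts a cohort
#' tibble or a CSV path. When paired columns `<marker>_t1` / `<marker>_t2`
#' and an interval are present, evolution (`_plus`) markers are computed
#' first and evaluated alongside the baseline (`_t1`) values.
#'
#' @param cohort Data frame or CSV path with an `outcome` column.
#' @param markers Marker column names; for paired cohorts, base names of
#'   `_t1`/`_t2` column pairs.
#' @param config A [run_config()].
#' @param out_json Optional path for a JSON report.
#' @return Tibble, one row per evaluated marker (see [evaluate_markers()]).
#' @export
run_evaluate <- function(cohort, markers, config = run_config(),
                         out_json = NULL) {
  data <- if (is.character(cohort)) read_cohort_csv(cohort) else tibble::as_tibble(cohort)
  if (!"outcome" %in% names(data)) abort("cohort must have an outcome column")

  paired <- markers[paste0(markers, "_t1") %in% names(data) &
                      paste0(markers, "_t2") %in% names(data)]
  eval_cols <- setdiff(markers, paired)
  if (length(paired)) {
    data <- annualize_cohort(data, paired, year_length = config$year_length)
    eval_cols <- c(eval_cols, paste0(paired, "_t1"), paste0(paired, "_plus"))
  }
  report <- evaluate_markers(data, eval_cols, outcome = "outcome",
                             level = config$ci_level)
  if (!is.null(out_json)) {
    jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  report
}
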