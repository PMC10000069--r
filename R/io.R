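# CSV input/output for observations and baselines, the JSON assessment
# report, and the end-to-end run used by the command-line interface.

OBS_COLUMNS <- c("study_id", "phase_id", "group_id", "animal_id",
                 "timepoint", "criterion", "value", "status")
BASELINE_COLUMNS <- c("animal_id", "criterion", "baseline_value")
REPORT_FORMAT_VERSION <- 1L

#' Read an observation table
#'
#' Long-format CSV, UTF-8, dot decimal separator, header exactly
#' `study_id,phase_id,group_id,animal_id,timepoint,criterion,value,status`.
#' One row per measurement; `value` may be empty only for `dead` or
#' `removed` rows.
#'
#' @param path CSV file path.
#' @return A tibble of observation records with a `.row` column holding
#'   the source line for error reporting.
#' @examples
#' fx <- rat_toxicity_example()
#' f <- tempfile(fileext = ".csv")
#' write_observations(fx$observations, f)
#' read_observations(f)
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("observation file not found: %s", path))
  }
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  missing_cols <- setdiff(OBS_COLUMNS, trimws(header))
  if (length(missing_cols)) {
    rlang::abort(sprintf("observation file missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  obs <- readr::read_csv(
    path,
    col_types = readr::cols(
      study_id = readr::col_character(),
      phase_id = readr::col_character(),
      group_id = readr::col_character(),
      animal_id = readr::col_character(),
      timepoint = readr::col_character(),
      criterion = readr::col_character(),
      value = readr::col_character(),
      status = readr::col_character()
    )
  )
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols)) {
    rlang::abort(sprintf("observation file missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  obs$.row <- seq_len(nrow(obs)) + 1L  # header is line 1
  bad_status <- !obs$status %in% c("alive", "dead", "removed")
  if (any(bad_status)) {
    rlang::abort(sprintf(
      "unknown status token '%s' at row %d",
      obs$status[which(bad_status)[1]], obs$.row[which(bad_status)[1]]
    ))
  }
  value <- suppressWarnings(as.numeric(obs$value))
  bad_num <- obs$status == "alive" & !is.na(obs$value) & is.na(value)
  if (any(bad_num)) {
    rlang::abort(sprintf(
      "non-numeric value '%s' for alive animal at row %d",
      obs$value[which(bad_num)[1]], obs$.row[which(bad_num)[1]]
    ))
  }
  empty_alive <- obs$status == "alive" &
    (is.na(obs$value) | !nzchar(trimws(obs$value)))
  if (any(empty_alive)) {
    rlang::abort(sprintf(
      "missing value for alive animal at row %d",
      obs$.row[which(empty_alive)[1]]
    ))
  }
  obs$value <- value
  obs[, c(OBS_COLUMNS, ".row")]
}

#' @param observations Observation tibble to write.
#' @rdname read_observations
#' @export
write_observations <- function(observations, path) {
  observations |>
    dplyr::select(dplyr::all_of(OBS_COLUMNS)) |>
    readr::write_csv(path)
  invisible(path)
}

#' Read a baseline table
#'
#' CSV with header exactly `animal_id,criterion,baseline_value`.
#'
#' @param path CSV file path.
#' @return Tibble of baselines.
#' @export
read_baselines <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("baseline file not found: %s", path))
  }
  bl <- readr::read_csv(
    path,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      criterion = readr::col_character(),
      baseline_value = readr::col_double()
    )
  )
  missing_cols <- setdiff(BASELINE_COLUMNS, names(bl))
  if (length(missing_cols)) {
    rlang::abort(sprintf("baseline file missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(bl$baseline_value))) {
    rlang::abort("baseline_value must be finite")
  }
  bl[, BASELINE_COLUMNS]
}

#' @param baselines Baseline tibble to write.
#' @rdname read_baselines
#' @export
write_baselines <- function(baselines, path) {
  baselines |>
    dplyr::select(dplyr::all_of(BASELINE_COLUMNS)) |>
    readr::write_csv(path)
  invisible(path)
}

#' Build the assessment report
#'
#' Assembles the JSON-serialisable report for a severity assessment. Every
#' number is derived from the stored score matrix; headline figures are
#' rendered to two decimals with full-precision values under `raw`.
#' Run metadata (timestamp) is isolated in a `meta` field so reports from
#' identical inputs are otherwise identical.
#'
#' @param assessment A `severity_assessment` from [assess_study()].
#' @return A named list ready for [jsonlite::write_json()].
#' @export
build_report <- function(assessment) {
  stopifnot(inherits(assessment, "severity_assessment"))
  ga <- assessment$group_assessments
  per_timepoint <- purrr::pmap(ga, function(group_id, timepoint, n_animals,
                                            n_criteria, overall_score,
                                            per_animal_average,
                                            criterion_averages,
                                            individual_scores) {
    list(
      group_id = group_id,
      timepoint = as.character(timepoint),
      n_animals = n_animals,
      criterion_averages = purrr::pmap(criterion_averages,
        function(criterion, total_score, n_animals, average, ...) {
          list(criterion = criterion, total_score = total_score,
               n_animals = n_animals, average = round(average, 2),
               raw = list(average = average))
        }),
      overall_score = round(overall_score, 2),
      per_animal_average = round(per_animal_average, 2),
      individual_scores = purrr::pmap(individual_scores,
        function(animal_id, individual_score, n_criteria, death_flag) {
          list(animal_id = animal_id, score = round(individual_score, 2),
               death = death_flag, raw = list(score = individual_score))
        }),
      raw = list(overall_score = overall_score,
                 per_animal_average = per_animal_average)
    )
  })
  verdict_rows <- tibble::as_tibble(assessment$limit_verdicts)
  phases <- NULL
  if (!is.null(assessment$phases)) {
    cum <- assessment$phases$cumulative
    phases <- list(
      per_phase = purrr::pmap(
        assessment$phases$per_phase |>
          dplyr::mutate(classification = as.character(.data$classification)),
        function(phase_id, per_animal_average, classification, ...) {
          list(phase_id = phase_id,
               per_animal_average = round(per_animal_average, 2),
               classification = classification,
               raw = list(per_animal_average = per_animal_average))
        }),
      cumulative = list(
        mode = cum$mode,
        classification = cum$classification,
        cumulative_load = if (is.na(cum$cumulative_load)) NULL else
          round(cum$cumulative_load, 2)
      )
    )
  }
  list(
    format_version = REPORT_FORMAT_VERSION,
    scheme = list(
      criteria = purrr::pmap(tidy(assessment$scheme), function(...) list(...)),
      severity_limits = as.list(assessment$scheme$severity_limits),
      predicted_classifications =
        as.list(assessment$scheme$predicted_classifications)
    ),
    per_timepoint = per_timepoint,
    per_group = purrr::pmap(assessment$classification_verdicts,
      function(group_id, worst_timepoint, per_animal_average, predicted,
               outcome) {
        list(group_id = group_id,
             worst_timepoint = as.character(worst_timepoint),
             per_animal_average = round(per_animal_average, 2),
             predicted = predicted, outcome = outcome,
             raw = list(per_animal_average = per_animal_average))
      }),
    verdicts = purrr::pmap(verdict_rows, function(group_id, timepoint,
                                                  animal_id, individual_score,
                                                  n_criteria, death_flag,
                                                  limit, limit_ordinal,
                                                  breached,
                                                  recommended_action) {
      list(group_id = group_id, timepoint = as.character(timepoint),
           animal_id = animal_id, individual_score = round(individual_score, 2),
           limit = limit, breached = breached,
           recommended_action = recommended_action,
           raw = list(individual_score = individual_score))
    }),
    phases = phases,
    audit = list(
      n_excluded_cells = nrow(assessment$audit),
      excluded = purrr::pmap(
        assessment$audit |>
          dplyr::select("group_id", "animal_id", "timepoint", "criterion",
                        "status"),
        function(group_id, animal_id, timepoint, criterion, status) {
          list(group_id = group_id, animal_id = animal_id,
               timepoint = as.character(timepoint), criterion = criterion,
               status = status)
        })
    ),
    any_breach = assessment$any_breach,
    meta = list(generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
}

#' Run a full assessment from files
#'
#' End-to-end entry point behind the command-line interface: read the
#' scheme, observations and baselines, assess, and write the JSON report
#' plus a flat verdict CSV suitable for score-sheet use.
#'
#' @param scheme_path Scheme YAML/JSON file.
#' @param observations_path,baselines_path Input CSV files.
#' @param output_path Path of the JSON report to write; the verdict CSV is
#'   written next to it with suffix `_verdicts.csv`.
#' @param control_group,cumulative_mode Passed to [assess_study()].
#' @return The `severity_assessment`, invisibly. Its `any_breach` element
#'   is what shell pipelines gate on (the CLI exits 2 on breach).
#' @examples
#' fx <- rat_toxicity_example()
#' d <- tempfile(); dir.create(d)
#' write_scheme(fx$scheme, file.path(d, "scheme.yaml"))
#' write_observations(fx$observations, file.path(d, "obs.csv"))
#' write_baselines(fx$baselines, file.path(d, "bl.csv"))
#' a <- run_assessment(file.path(d, "scheme.yaml"), file.path(d, "obs.csv"),
#'                     file.path(d, "bl.csv"), file.path(d, "report.json"))
#' a$any_breach
#' @export
run_assessment <- function(scheme_path, observations_path, baselines_path,
                           output_path, control_group = NULL,
                           cumulative_mode = "max") {
  scheme <- read_scheme(scheme_path)
  observations <- read_observations(observations_path)
  baselines <- read_baselines(baselines_path)
  if (nrow(observations) == 0L) {
    rlang::abort("empty observation file: nothing to assess")
  }
  assessment <- assess_study(observations, baselines, scheme,
                             control_group = control_group,
                             cumulative_mode = cumulative_mode)
  report <- build_report(assessment)
  jsonlite::write_json(report, output_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  verdict_csv <- sub("\\.json$", "", output_path)
  verdict_csv <- paste0(verdict_csv, "_verdicts.csv")
  assessment$limit_verdicts |>
    tibble::as_tibble() |>
    dplyr::mutate(timepoint = as.character(.data$timepoint)) |>
    readr::write_csv(verdict_csv)
  invisible(assessment)
}
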