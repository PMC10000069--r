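# Converting raw measurements into ordinal severity scores: deviation from
# baseline, band assignment, and per-timepoint score matrices with the
# death override.

#' Deviation of a measurement from its baseline
#'
#' Computes the non-negative deviation, in band units, of a measured value
#' from the animal's baseline under a band scheme. For `absolute` schemes
#' the deviation is the directed difference in criterion units; for
#' `percent` schemes it is `100 * (value - baseline) / baseline`. Under
#' one-sided directions (`increase`, `decrease`) excursions in the opposite
#' direction map to zero deviation; `either` returns the magnitude.
#'
#' @param value Numeric measurement(s) in criterion units.
#' @param baseline Numeric baseline value(s), recycled against `value`.
#'   Must be finite; strictly positive for `percent` schemes.
#' @param bands A [band_scheme()].
#' @return Non-negative numeric deviation(s) in band units (criterion units
#'   for `absolute`, percent of baseline for `percent`).
#' @examples
#' b <- band_scheme(c(0.2, 1, 2, 3), "absolute", "increase")
#' deviation(39.0, 38.0, b)   # 1.0 degree rise
#' w <- band_scheme(c(5, 10, 20, 30), "percent", "decrease")
#' deviation(190, 200, w)     # 5 percent loss
#' @export
deviation <- function(value, baseline, bands) {
  stopifnot(inherits(bands, "band_scheme"))
  if (any(!is.finite(value))) {
    rlang::abort("`value` must be finite")
  }
  if (any(!is.finite(baseline))) {
    rlang::abort("`baseline` must be finite")
  }
  diff <- value - baseline
  if (bands$deviation_kind == "percent") {
    if (any(baseline <= 0)) {
      rlang::abort("percent deviation requires strictly positive baselines")
    }
    diff <- 100 * diff / baseline
  }
  out <- switch(bands$direction,
    increase = pmax(diff, 0),
    decrease = pmax(-diff, 0),
    either   = abs(diff)
  )
  opposite <- switch(bands$direction,
    increase = diff < 0,
    decrease = diff > 0,
    either   = rep(FALSE, length(diff))
  )
  if (any(opposite)) {
    rlang::warn(sprintf(
      "%d measurement(s) deviated opposite to the scheme direction (%s) and scored 0",
      sum(opposite), bands$direction
    ))
  }
  out
}

#' Assign a deviation to its severity band
#'
#' Returns the ordinal score 0-4 of the unique band containing the
#' deviation. Bands are closed on the right: a deviation exactly equal to a
#' boundary falls in the lower band, so with temperature boundaries
#' 0.2/1/2/3 a rise of exactly 1.0 scores 1 (mild).
#'
#' @param dev Non-negative numeric deviation(s) in band units.
#' @param bands A [band_scheme()].
#' @return Integer score(s) in 0-4. `NA` deviations give `NA` scores.
#' @examples
#' b <- band_scheme(c(0.2, 1, 2, 3), "absolute", "increase")
#' assign_band(c(0, 0.5, 1.0, 2.5, 10), b)  # 0 1 1 3 4
#' @export
assign_band <- function(dev, bands) {
  stopifnot(inherits(bands, "band_scheme"))
  if (any(dev < 0, na.rm = TRUE)) {
    rlang::abort("deviation must be non-negative (direction handling happens upstream)")
  }
  out <- rep(NA_integer_, length(dev))
  ok <- !is.na(dev)
  # bands are (b_{k-1}, b_k]: count boundaries strictly below the deviation
  out[ok] <- findInterval(dev[ok], bands$boundaries, left.open = TRUE)
  out
}

# Timepoints are opaque ordered labels. Order: factor levels if already a
# factor, else order of first appearance in the data.
timepoint_levels <- function(x) {
  if (is.factor(x)) levels(x) else unique(as.character(x))
}

#' Score observations into a long score matrix
#'
#' Converts a long observation table into per-animal, per-criterion,
#' per-timepoint ordinal severity scores under a scheme set. Alive animals
#' are scored by banding their deviation from baseline. Dead animals score
#' 4 on every criterion at the death timepoint and all later timepoints
#' (death is a serious adverse effect in its own right, regardless of
#' measurements). Removed (withdrawn) animals are marked missing from that
#' timepoint on and excluded from group statistics, but their rows are
#' retained for the audit trail.
#'
#' @param observations Tibble/data frame with columns `study_id`,
#'   `phase_id`, `group_id`, `animal_id`, `timepoint`, `criterion`,
#'   `value`, `status` (`alive`, `dead`, `removed`). `value` must be
#'   present iff `status == "alive"`.
#' @param baselines Tibble with columns `animal_id`, `criterion`,
#'   `baseline_value` for every `self_baseline` criterion; for
#'   `control_mean` criteria the baseline is the mean of `control_group`'s
#'   values at the same timepoint.
#' @param scheme A [scheme_set()].
#' @param control_group Group id supplying control-mean baselines; only
#'   needed when a criterion uses `baseline_source = "control_mean"`.
#' @return A `score_matrix` tibble with columns `study_id`, `phase_id`,
#'   `group_id`, `animal_id`, `timepoint` (factor, ordered), `criterion`,
#'   `value`, `deviation`, `score` (integer 0-4 or `NA`), `status`,
#'   `death_flag`, `included` (logical: counts towards group statistics).
#' @examples
#' fx <- rat_toxicity_example()
#' score_observations(fx$observations, fx$baselines, fx$scheme)
#' @export
score_observations <- function(observations, baselines, scheme,
                               control_group = NULL) {
  stopifnot(inherits(scheme, "scheme_set"))
  obs <- tibble::as_tibble(observations)
  required <- c("study_id", "phase_id", "group_id", "animal_id",
                "timepoint", "criterion", "value", "status")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    rlang::abort(sprintf("observations missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (nrow(obs) == 0L) {
    return(empty_score_matrix())
  }
  bad_status <- setdiff(unique(obs$status), c("alive", "dead", "removed"))
  if (length(bad_status)) {
    rlang::abort(sprintf("unknown status token(s): %s",
                         paste(bad_status, collapse = ", ")))
  }
  unknown <- setdiff(unique(obs$criterion), names(scheme$criteria))
  if (length(unknown)) {
    rlang::abort(sprintf("observation references unknown criterion: %s",
                         paste(unknown, collapse = ", ")))
  }
  dup <- obs |>
    dplyr::count(.data$animal_id, .data$timepoint, .data$criterion) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    rlang::abort(sprintf(
      "duplicate (animal, timepoint, criterion) record(s): %s",
      paste(utils::head(sprintf("(%s, %s, %s)", dup$animal_id,
                                dup$timepoint, dup$criterion), 5),
            collapse = "; ")
    ))
  }
  if (any(obs$status == "alive" & is.na(obs$value))) {
    rlang::warn("alive observation(s) with missing value: cell left missing and excluded from group denominators")
  }

  tp_levels <- timepoint_levels(obs$timepoint)
  obs$timepoint <- factor(as.character(obs$timepoint), levels = tp_levels,
                          ordered = TRUE)

  # Expand to the full animal x criterion grid at each observed timepoint of
  # each animal, so the death override covers criteria with no record.
  grid <- obs |>
    dplyr::distinct(.data$study_id, .data$phase_id, .data$group_id,
                    .data$animal_id, .data$timepoint) |>
    tidyr::crossing(criterion = names(scheme$criteria))
  scored <- grid |>
    dplyr::left_join(
      obs |> dplyr::select(dplyr::all_of(required)),
      by = c("study_id", "phase_id", "group_id", "animal_id",
             "timepoint", "criterion")
    )
  # status of the animal at a timepoint: worst status among its records there
  status_rank <- c(alive = 1L, removed = 2L, dead = 3L)
  tp_status <- obs |>
    dplyr::group_by(.data$animal_id, .data$timepoint) |>
    dplyr::summarise(
      tp_status = names(status_rank)[max(status_rank[.data$status])],
      .groups = "drop"
    )
  scored <- scored |>
    dplyr::left_join(tp_status, by = c("animal_id", "timepoint")) |>
    dplyr::mutate(status = dplyr::coalesce(.data$status, .data$tp_status))

  # baselines: self per animal x criterion; control mean per timepoint
  bl <- tibble::as_tibble(baselines)
  if (nrow(bl) > 0 &&
      !all(c("animal_id", "criterion", "baseline_value") %in% names(bl))) {
    rlang::abort("baselines must have columns animal_id, criterion, baseline_value")
  }

  parts <- purrr::map(scheme$criteria, function(cr) {
    rows <- scored |> dplyr::filter(.data$criterion == cr$name)
    if (nrow(rows) == 0L) return(rows |> dplyr::mutate(deviation = double(0)))
    if (cr$baseline_source == "self_baseline") {
      this_bl <- bl |>
        dplyr::filter(.data$criterion == cr$name) |>
        dplyr::select("animal_id", "baseline_value")
      rows <- rows |> dplyr::left_join(this_bl, by = "animal_id")
    } else {
      if (is.null(control_group)) {
        rlang::abort(sprintf(
          "criterion '%s' uses control_mean baselines but no control_group was given",
          cr$name
        ))
      }
      ctrl <- rows |>
        dplyr::filter(.data$group_id == control_group,
                      .data$status == "alive", !is.na(.data$value)) |>
        dplyr::group_by(.data$timepoint) |>
        dplyr::summarise(baseline_value = mean(.data$value), .groups = "drop")
      rows <- rows |> dplyr::left_join(ctrl, by = "timepoint")
    }
    alive_scored <- rows$status == "alive" & !is.na(rows$value)
    no_baseline <- alive_scored & is.na(rows$baseline_value)
    if (any(no_baseline)) {
      rlang::abort(sprintf(
        "no baseline for criterion '%s', animal(s): %s",
        cr$name,
        paste(unique(rows$animal_id[no_baseline]), collapse = ", ")
      ))
    }
    rows$deviation <- NA_real_
    idx <- which(alive_scored)
    if (length(idx)) {
      rows$deviation[idx] <- deviation(rows$value[idx],
                                       rows$baseline_value[idx], cr$bands)
    }
    rows$score <- NA_integer_
    rows$score[idx] <- assign_band(rows$deviation[idx], cr$bands)
    rows |> dplyr::select(-"baseline_value")
  })
  out <- dplyr::bind_rows(parts)

  # death override: score 4 at the death timepoint and every later one
  dead_rows <- out |> dplyr::filter(.data$status == "dead")
  death_onset <- if (nrow(dead_rows)) {
    dead_rows |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::summarise(death_tp = min(.data$timepoint), .groups = "drop")
  } else {
    tibble::tibble(animal_id = character(),
                   death_tp = factor(character(), levels = tp_levels,
                                     ordered = TRUE))
  }
  out <- out |>
    dplyr::left_join(death_onset, by = "animal_id") |>
    dplyr::mutate(
      death_flag = !is.na(.data$death_tp) & .data$timepoint >= .data$death_tp,
      score = dplyr::if_else(.data$death_flag, 4L, .data$score),
      status = dplyr::if_else(.data$death_flag, "dead", .data$status)
    ) |>
    dplyr::select(-"death_tp", -"tp_status")

  # removed animals: last score retained in the row, excluded from stats
  out <- out |>
    dplyr::mutate(included = .data$status != "removed" & !is.na(.data$score)) |>
    dplyr::arrange(.data$group_id, .data$animal_id, .data$timepoint,
                   .data$criterion)
  class(out) <- c("score_matrix", class(out))
  out
}

empty_score_matrix <- function() {
  out <- tibble::tibble(
    study_id = character(), phase_id = character(), group_id = character(),
    animal_id = character(),
    timepoint = factor(character(), ordered = TRUE),
    criterion = character(), value = double(), deviation = double(),
    score = integer(), status = character(), death_flag = logical(),
    included = logical()
  )
  class(out) <- c("score_matrix", class(out))
  out
}

#' Pivot a score matrix to wide animal-by-criterion form
#'
#' @param scores A `score_matrix` from [score_observations()].
#' @return A tibble with one row per animal and timepoint and one column
#'   per criterion, holding the ordinal scores (the layout of a printed
#'   score sheet).
#' @examples
#' fx <- rat_toxicity_example()
#' score_wide(score_observations(fx$observations, fx$baselines, fx$scheme))
#' @export
score_wide <- function(scores) {
  scores |>
    dplyr::select("group_id", "animal_id", "timepoint", "criterion",
                  "score") |>
    tidyr::pivot_wider(names_from = "criterion", values_from = "score") |>
    dplyr::arrange(.data$group_id, .data$timepoint, .data$animal_id)
}

#' Plot a score matrix as a severity heatmap
#'
#' @param object A `score_matrix`.
#' @param ... Unused.
#' @return A ggplot: animals against timepoints, tiles filled by ordinal
#'   score, faceted by criterion.
#' @export
autoplot.score_matrix <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$timepoint, y = .data$animal_id,
                 fill = factor(.data$score, levels = 0:4))
  ) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::facet_grid(.data$group_id ~ .data$criterion,
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_manual(
      values = c(`0` = "#4daf4a", `1` = "#ffff99", `2` = "#ff7f00",
                 `3` = "#e41a1c", `4` = "#67000d"),
      na.value = "grey85", drop = FALSE, name = "score"
    ) +
    ggplot2::labs(x = "timepoint", y = "animal",
                  title = "Severity scores by animal and criterion") +
    ggplot2::theme_minimal()
}
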