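# Group statistics: per-criterion group averages, the overall impact score
# N x mean(criterion averages), per-animal average impact, and individual
# animal scores.

#' Group average score for each criterion
#'
#' For every group, timepoint and criterion, sums the ordinal scores of the
#' scored animals and divides by their number. This is the "group average"
#' of the scoring matrix: e.g. temperature scores (0, 1, 0, 1, 1) over five
#' animals give total 3 and average 0.6.
#'
#' @param scores A `score_matrix` from [score_observations()], or any
#'   tibble with columns `group_id`, `timepoint`, `criterion`, `animal_id`,
#'   `score` (an `included` column, if present, restricts the denominator).
#' @return A tibble with one row per group x timepoint x criterion:
#'   `total_score`, `n_animals` (scored animals only) and `average`.
#' @examples
#' fx <- rat_toxicity_example()
#' sc <- score_observations(fx$observations, fx$baselines, fx$scheme)
#' group_criterion_average(sc)
#' @export
group_criterion_average <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (!"included" %in% names(scores)) {
    scores$included <- !is.na(scores$score)
  }
  all_missing <- scores |>
    dplyr::group_by(.data$group_id, .data$timepoint, .data$criterion) |>
    dplyr::summarise(n = sum(.data$included), .groups = "drop") |>
    dplyr::filter(.data$n == 0L)
  if (nrow(all_missing)) {
    rlang::abort(sprintf(
      "no scored animals for group/criterion/timepoint: %s",
      paste(sprintf("(%s, %s, %s)", all_missing$group_id,
                    all_missing$criterion, all_missing$timepoint),
            collapse = "; ")
    ))
  }
  scores |>
    dplyr::filter(.data$included) |>
    dplyr::group_by(.data$group_id, .data$timepoint, .data$criterion) |>
    dplyr::summarise(
      total_score = sum(.data$score),
      n_animals = dplyr::n_distinct(.data$animal_id),
      average = .data$total_score / .data$n_animals,
      .groups = "drop"
    )
}

#' Overall impact score for a group
#'
#' The overall impact score is the number of animals times the mean of the
#' group's criterion averages: with two criteria,
#' `N x (avg1 + avg2) / 2`. The formula generalises to K criteria by
#' dividing by K, weighting criteria equally.
#'
#' @param criterion_averages Numeric vector of per-criterion group
#'   averages (each in 0-4).
#' @param n_animals Number of animals in the group (>= 1).
#' @return The overall impact score, in `[0, 4 * n_animals]`.
#' @examples
#' overall_impact_score(c(0.6, 1.2), 5)  # 4.5
#' overall_impact_score(c(3, 3.2), 5)    # 15.5
#' @export
overall_impact_score <- function(criterion_averages, n_animals) {
  if (length(criterion_averages) == 0L) {
    rlang::abort("at least one criterion average is required")
  }
  if (n_animals < 1) {
    rlang::abort("`n_animals` must be at least 1")
  }
  n_animals * mean(criterion_averages)
}

#' Per-animal average impact score
#'
#' The overall impact score spread back over the animals of the group:
#' `overall / n_animals`. This is the figure compared against the group's
#' predicted severity classification (an average of 1 corresponds to every
#' animal sitting in the mild band).
#'
#' @param overall_score Overall impact score from [overall_impact_score()].
#' @param n_animals Number of animals (>= 1).
#' @return The per-animal average impact, in `[0, 4]`.
#' @examples
#' per_animal_average(4.5, 5)   # 0.9
#' per_animal_average(15.5, 5)  # 3.1
#' @export
per_animal_average <- function(overall_score, n_animals) {
  if (any(n_animals < 1)) {
    rlang::abort("`n_animals` must be at least 1")
  }
  overall_score / n_animals
}

#' Individual animal impact scores
#'
#' The mean of each animal's non-missing criterion scores at each
#' timepoint: the per-animal figure checked against the individual
#' severity limit.
#'
#' @param scores A `score_matrix` (or compatible tibble).
#' @return A tibble with one row per group x timepoint x animal:
#'   `individual_score` (in 0-4), `n_criteria` scored, and `death_flag`
#'   when present in the input.
#' @examples
#' fx <- rat_toxicity_example()
#' sc <- score_observations(fx$observations, fx$baselines, fx$scheme)
#' individual_animal_score(sc)
#' @export
individual_animal_score <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (!"included" %in% names(scores)) {
    scores$included <- !is.na(scores$score)
  }
  if (!"death_flag" %in% names(scores)) {
    scores$death_flag <- FALSE
  }
  out <- scores |>
    dplyr::group_by(.data$group_id, .data$timepoint, .data$animal_id) |>
    dplyr::summarise(
      individual_score = mean(.data$score[.data$included]),
      n_criteria = sum(.data$included),
      death_flag = any(.data$death_flag),
      .groups = "drop"
    )
  empty <- out |> dplyr::filter(.data$n_criteria == 0L)
  if (nrow(empty)) {
    rlang::abort(sprintf(
      "animal(s) with no scored criteria: %s",
      paste(sprintf("(%s at %s)", empty$animal_id, empty$timepoint),
            collapse = "; ")
    ))
  }
  out
}

#' Aggregate a score matrix into group assessments
#'
#' Runs the full aggregation chain for every group and timepoint: criterion
#' averages, overall impact score, per-animal average impact, and
#' individual animal scores.
#'
#' @param scores A `score_matrix` from [score_observations()].
#' @return A `group_assessment` tibble, one row per group x timepoint:
#'   `n_animals`, `n_criteria`, `overall_score`, `per_animal_average`,
#'   plus list-columns `criterion_averages` (tibbles from
#'   [group_criterion_average()]) and `individual_scores` (tibbles from
#'   [individual_animal_score()]).
#' @examples
#' fx <- rat_toxicity_example()
#' sc <- score_observations(fx$observations, fx$baselines, fx$scheme)
#' aggregate_scores(sc)
#' @export
aggregate_scores <- function(scores) {
  crit_avg <- group_criterion_average(scores)
  indiv <- individual_animal_score(scores)
  out <- crit_avg |>
    dplyr::group_by(.data$group_id, .data$timepoint) |>
    dplyr::summarise(
      n_animals = max(.data$n_animals),
      n_criteria = dplyr::n(),
      overall_score = overall_impact_score(.data$average, max(.data$n_animals)),
      criterion_averages = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      per_animal_average = per_animal_average(.data$overall_score,
                                              .data$n_animals)
    ) |>
    dplyr::left_join(
      indiv |>
        tidyr::nest(individual_scores = c("animal_id", "individual_score",
                                          "n_criteria", "death_flag")),
      by = c("group_id", "timepoint")
    ) |>
    dplyr::select("group_id", "timepoint", "n_animals", "n_criteria",
                  "overall_score", "per_animal_average",
                  "criterion_averages", "individual_scores")
  class(out) <- c("group_assessment", class(out))
  out
}

#' Plot group severity trajectories
#'
#' @param object A `group_assessment` from [aggregate_scores()].
#' @param ... Unused.
#' @return A ggplot of per-animal average impact over timepoints, one line
#'   per group, with horizontal guides at the severity category ordinals.
#' @export
autoplot.group_assessment <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$timepoint, y = .data$per_animal_average,
                 colour = .data$group_id, group = .data$group_id)
  ) +
    ggplot2::geom_hline(yintercept = 0:4, linetype = "dotted",
                        colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(
      limits = c(0, 4),
      breaks = 0:4,
      labels = sprintf("%d (%s)", 0:4, severity_levels())
    ) +
    ggplot2::labs(x = "timepoint", y = "per-animal average impact",
                  colour = "group",
                  title = "Group severity trajectories") +
    ggplot2::theme_minimal()
}
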