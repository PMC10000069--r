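# Turning scores into verdicts: individual severity-limit breaches,
# group/project severity-classification comparison, cumulative severity
# across phases, and reuse eligibility.

#' Check individual scores against a severity limit
#'
#' An animal breaches its group's severity limit when its individual score
#' strictly exceeds the limit's ordinal (an average of exactly 3 against a
#' severe limit is at, not over, the limit; 3.1 is a breach). Breaching
#' animals carry the advisory action `alert_licence_holder`, escalated to
#' `humane_kill_candidate` at a score of 4. Verdicts are advisory only:
#' breaching animals' scores stay on record.
#'
#' @param individual_scores Tibble with columns `animal_id` and
#'   `individual_score` (from [individual_animal_score()]); extra columns
#'   such as `timepoint` and `group_id` are carried through.
#' @param limit Severity category (label or ordinal 0-4): the group's
#'   individual severity limit.
#' @return A `limit_verdicts` tibble adding `limit`, `limit_ordinal`,
#'   `breached` and `recommended_action`
#'   (`none`, `alert_licence_holder`, `withdraw_or_treat`,
#'   `humane_kill_candidate`).
#' @examples
#' scores <- tibble::tibble(animal_id = c("a1", "a2"),
#'                          individual_score = c(4, 0.5))
#' check_severity_limit(scores, "severe")
#' @export
check_severity_limit <- function(individual_scores, limit) {
  limit <- as_severity(limit)
  if (length(limit) != 1L || is.na(limit)) {
    rlang::abort("`limit` must be a single severity category")
  }
  scores <- tibble::as_tibble(individual_scores)
  if (any(scores$individual_score < 0 | scores$individual_score > 4)) {
    rlang::abort("individual scores must lie in [0, 4]")
  }
  lim_ord <- severity_ordinal(limit)
  out <- scores |>
    dplyr::mutate(
      limit = as.character(limit),
      limit_ordinal = lim_ord,
      breached = .data$individual_score > lim_ord,
      recommended_action = dplyr::case_when(
        .data$breached & .data$individual_score >= 4 ~ "humane_kill_candidate",
        .data$breached & .data$individual_score >= lim_ord + 1 ~ "withdraw_or_treat",
        .data$breached ~ "alert_licence_holder",
        TRUE ~ "none"
      )
    )
  class(out) <- c("limit_verdicts", class(out))
  out
}

#' Compare a per-animal average with the predicted classification
#'
#' The predicted severity classification of a group corresponds to its
#' ordinal: a mild prediction means each animal should average 1. The
#' actual per-animal average is `under` the prediction when strictly less
#' than the ordinal, `met` when exactly equal, and `exceeded` when
#' strictly greater (0.9 against mild is under; 3.1 against severe is
#' exceeded).
#'
#' @param per_animal_avg Numeric per-animal average impact score(s), each
#'   in 0-4.
#' @param predicted Severity category (label or ordinal), recycled against
#'   `per_animal_avg`.
#' @return A tibble with `per_animal_average`, `predicted`,
#'   `predicted_ordinal` and `outcome` (`under`/`met`/`exceeded`).
#' @examples
#' compare_classification(0.9, "mild")     # under
#' compare_classification(3.1, "severe")   # exceeded
#' @export
compare_classification <- function(per_animal_avg, predicted) {
  if (any(per_animal_avg < 0 | per_animal_avg > 4)) {
    rlang::abort("per-animal averages must lie in [0, 4]")
  }
  predicted <- as_severity(predicted)
  ord <- severity_ordinal(predicted)
  tibble::tibble(
    per_animal_average = per_animal_avg,
    predicted = as.character(predicted),
    predicted_ordinal = ord,
    outcome = dplyr::case_when(
      per_animal_avg < ord ~ "under",
      per_animal_avg == ord ~ "met",
      TRUE ~ "exceeded"
    )
  )
}

#' Cumulative severity over the phases of a project
#'
#' In continued use, each phase of a project is scored separately; the
#' project-level severity is derived from the per-phase outcomes. The
#' default `max` mode reports the highest phase classification (the
#' regulatory "actual severity" convention). `sum` mode additionally
#' reports the arithmetic total of the phase per-animal averages as a
#' cumulative-load index. The per-phase breakdown is always returned.
#'
#' @param phase_results Tibble with one row per phase: `phase_id`,
#'   `classification` (severity label or ordinal) and, for `sum` mode,
#'   `per_animal_average`.
#' @param mode `"max"` (default) or `"sum"`.
#' @return A list with `mode`, `classification` (the project-level
#'   category label), `cumulative_load` (`sum` mode only, else `NA`), and
#'   `phases` (the input with ordinals attached).
#' @examples
#' ph <- tibble::tibble(phase_id = c("surgery", "treatment"),
#'                      classification = c("moderate", "mild"),
#'                      per_animal_average = c(1.8, 0.9))
#' cumulative_severity(ph)
#' cumulative_severity(ph, mode = "sum")
#' @export
cumulative_severity <- function(phase_results, mode = c("max", "sum")) {
  mode <- rlang::arg_match(mode)
  phases <- tibble::as_tibble(phase_results)
  if (nrow(phases) == 0L) {
    rlang::abort("at least one phase is required")
  }
  phases$classification <- as_severity(phases$classification)
  phases$classification_ordinal <- severity_ordinal(phases$classification)
  overall <- phases$classification[which.max(phases$classification_ordinal)]
  load <- NA_real_
  if (mode == "sum") {
    if (!"per_animal_average" %in% names(phases)) {
      rlang::abort("`sum` mode requires a per_animal_average column")
    }
    load <- sum(phases$per_animal_average)
  }
  list(
    mode = mode,
    classification = as.character(overall),
    cumulative_load = load,
    phases = phases
  )
}

#' Reuse eligibility after a previous use
#'
#' An animal may be enrolled in a new project only if the actual severity
#' of its previous use did not exceed a policy threshold. The default
#' threshold is `moderate`, the usual reading of Directive 2010/63/EU
#' Art. 16.1(a); the threshold is an explicit argument because regulatory
#' interpretations differ (see the package vignette).
#'
#' @param prior_actual_severity Severity category of the previous use.
#' @param policy_threshold Maximum prior severity compatible with reuse.
#' @return `"eligible"` or `"ineligible"`.
#' @examples
#' reuse_eligibility("moderate")            # eligible (default threshold)
#' reuse_eligibility("severe")              # ineligible
#' reuse_eligibility("moderate", "mild")    # ineligible under stricter policy
#' @export
reuse_eligibility <- function(prior_actual_severity,
                              policy_threshold = "moderate") {
  prior <- severity_ordinal(prior_actual_severity)
  thr <- severity_ordinal(policy_threshold)
  ifelse(prior <= thr, "eligible", "ineligible")
}

#' Classify a per-animal average into a severity category
#'
#' Maps a continuous per-animal average onto the category whose ordinal it
#' rounds up to: averages at or below an ordinal fall in that category
#' (an average of exactly 3 is severe; 3.1 is beyond severe). Used to turn
#' phase averages into phase classifications.
#'
#' @param per_animal_avg Numeric average(s) in 0-4.
#' @return Ordered severity factor.
#' @examples
#' classify_average(c(0, 0.9, 1, 3.1))
#' @export
classify_average <- function(per_animal_avg) {
  if (any(per_animal_avg < 0 | per_animal_avg > 4)) {
    rlang::abort("per-animal averages must lie in [0, 4]")
  }
  as_severity(as.integer(ceiling(per_animal_avg)))
}

#' Full severity assessment of a study
#'
#' Runs the complete pipeline: score the observations, aggregate per group
#' and timepoint, check every animal against its group's individual
#' severity limit at every timepoint (a humane endpoint cannot be averaged
#' away, so an animal breaches if it exceeds the limit at any timepoint),
#' and compare each group's worst-case per-animal average against its
#' predicted severity classification.
#'
#' @param observations,baselines,scheme,control_group As in
#'   [score_observations()].
#' @param cumulative_mode Passed to [cumulative_severity()] when the study
#'   has more than one phase.
#' @return A `severity_assessment` object (list) with elements `scheme`,
#'   `scores` (the score matrix), `group_assessments`, `limit_verdicts`
#'   (all timepoints), `classification_verdicts` (worst case per group),
#'   `phases` (per-phase worst-case results and the cumulative summary, or
#'   `NULL` for single-phase studies), `audit` (rows excluded from group
#'   statistics) and `any_breach`.
#' @examples
#' fx <- rat_toxicity_example()
#' a <- assess_study(fx$observations, fx$baselines, fx$scheme)
#' glance(a)
#' @export
assess_study <- function(observations, baselines, scheme,
                         control_group = NULL,
                         cumulative_mode = c("max", "sum")) {
  cumulative_mode <- rlang::arg_match(cumulative_mode)
  scores <- score_observations(observations, baselines, scheme,
                               control_group = control_group)
  if (nrow(scores) == 0L) {
    rlang::abort("no observations to assess")
  }
  ga <- aggregate_scores(scores)
  indiv <- individual_animal_score(scores)

  limits <- scheme$severity_limits
  verdicts <- indiv |>
    dplyr::filter(.data$group_id %in% names(limits)) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::group_modify(function(df, key) {
      check_severity_limit(df, limits[[key$group_id]])
    }) |>
    dplyr::ungroup()
  class(verdicts) <- c("limit_verdicts", class(verdicts))

  preds <- scheme$predicted_classifications
  worst <- ga |>
    dplyr::group_by(.data$group_id) |>
    dplyr::slice_max(.data$per_animal_average, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  classification <- worst |>
    dplyr::filter(.data$group_id %in% names(preds)) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      verdict = list(compare_classification(
        .data$per_animal_average, preds[[.data$group_id]]
      ))
    ) |>
    dplyr::ungroup() |>
    tidyr::unnest("verdict", names_sep = ".") |>
    dplyr::transmute(
      group_id = .data$group_id,
      worst_timepoint = .data$timepoint,
      per_animal_average = .data$per_animal_average,
      predicted = .data$verdict.predicted,
      outcome = .data$verdict.outcome
    )

  phases <- NULL
  phase_ids <- unique(as.character(scores$phase_id))
  if (length(phase_ids) > 1L) {
    per_phase <- scores |>
      dplyr::group_by(.data$phase_id) |>
      dplyr::group_modify(function(df, key) {
        pg <- aggregate_scores(df)
        tibble::tibble(
          per_animal_average = max(pg$per_animal_average),
          classification = as.character(
            classify_average(max(pg$per_animal_average))
          )
        )
      }) |>
      dplyr::ungroup()
    phases <- list(
      per_phase = per_phase,
      cumulative = cumulative_severity(per_phase, mode = cumulative_mode)
    )
  }

  audit <- scores |> dplyr::filter(!.data$included)

  out <- list(
    scheme = scheme,
    scores = scores,
    group_assessments = ga,
    limit_verdicts = verdicts,
    classification_verdicts = classification,
    phases = phases,
    audit = audit,
    any_breach = any(verdicts$breached)
  )
  class(out) <- "severity_assessment"
  out
}

#' @export
print.severity_assessment <- function(x, ...) {
  cat("<severity_assessment>\n")
  cat(sprintf("  %d animals, %d criteria, %d timepoint(s), %d group(s)\n",
              dplyr::n_distinct(x$scores$animal_id),
              length(x$scheme$criteria),
              dplyr::n_distinct(x$scores$timepoint),
              dplyr::n_distinct(x$scores$group_id)))
  cat("  classification verdicts:\n")
  for (i in seq_len(nrow(x$classification_verdicts))) {
    v <- x$classification_verdicts[i, ]
    cat(sprintf("    %s: per-animal average %.2f vs predicted %s -> %s\n",
                v$group_id, v$per_animal_average, v$predicted, v$outcome))
  }
  nb <- sum(x$limit_verdicts$breached)
  cat(sprintf("  severity-limit breaches: %d animal-timepoint(s)\n", nb))
  invisible(x)
}

#' Tidy a severity assessment into per-animal verdicts
#'
#' @param x A `severity_assessment` from [assess_study()].
#' @param ... Unused.
#' @return The limit-verdict tibble: one row per animal x timepoint with
#'   individual score, limit, breach flag and recommended action.
#' @export
tidy.severity_assessment <- function(x, ...) {
  tibble::as_tibble(x$limit_verdicts)
}

#' One-row-per-group summary of a severity assessment
#'
#' @param x A `severity_assessment`.
#' @param ... Unused.
#' @return Tibble with per-group worst-case per-animal average, predicted
#'   classification, outcome, and number of breaching animals.
#' @export
glance.severity_assessment <- function(x, ...) {
  breaches <- x$limit_verdicts |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(n_breaching = dplyr::n_distinct(
      .data$animal_id[.data$breached]
    ), .groups = "drop")
  x$classification_verdicts |>
    dplyr::left_join(breaches, by = "group_id") |>
    dplyr::mutate(n_breaching = dplyr::coalesce(.data$n_breaching, 0L))
}

#' Plot a severity assessment
#'
#' @param object A `severity_assessment`.
#' @param ... Unused.
#' @return A ggplot of the group severity trajectories with each group's
#'   predicted classification drawn as a dashed reference line.
#' @export
autoplot.severity_assessment <- function(object, ...) {
  p <- autoplot.group_assessment(object$group_assessments)
  preds <- object$scheme$predicted_classifications
  if (length(preds)) {
    ref <- tibble::tibble(
      group_id = names(preds),
      predicted_ordinal = severity_ordinal(unname(preds))
    )
    p <- p + ggplot2::geom_hline(
      data = ref,
      ggplot2::aes(yintercept = .data$predicted_ordinal,
                   colour = .data$group_id),
      linetype = "dashed"
    )
  }
  p
}
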