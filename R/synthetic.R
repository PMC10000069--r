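# Synthetic cohorts with known band structure, and the built-in worked
# example reproducing the published low-dose/high-dose scoring matrices.

#' Specify a synthetic cohort
#'
#' A cohort spec fixes how many animals to simulate and, per criterion,
#' the probability of an animal landing in each of the five severity
#' bands. Measurements are then placed inside the drawn band, so the
#' scored band frequencies of a large cohort converge to the requested
#' probabilities.
#'
#' @param n_animals Number of animals (>= 1).
#' @param band_probabilities Either a single numeric vector of five
#'   probabilities (recycled over all criteria) or a named list mapping
#'   criterion name to such a vector. Probabilities must be non-negative
#'   and sum to 1.
#' @param within_band_placement `"midpoint"` (default; deviations sit at
#'   band centres, making the scored bands invariant to boundary-handling
#'   conventions) or `"uniform"` (deviations drawn uniformly inside the
#'   band, stress-testing boundary handling). The unbounded top band uses
#'   `1.5 * b3` as its midpoint surrogate and `(b3, 2 * b3]` for uniform
#'   draws.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `cohort_spec` object.
#' @examples
#' cohort_spec(10, c(0.2, 0.2, 0.2, 0.2, 0.2), seed = 1)
#' @export
cohort_spec <- function(n_animals, band_probabilities,
                        within_band_placement = c("midpoint", "uniform"),
                        seed = 1L) {
  within_band_placement <- rlang::arg_match(within_band_placement)
  if (n_animals < 1) {
    rlang::abort("`n_animals` must be at least 1")
  }
  check_probs <- function(p, label) {
    if (!is.numeric(p) || length(p) != 5L) {
      rlang::abort(sprintf(
        "%s: exactly five band probabilities are required", label
      ))
    }
    if (any(p < 0)) {
      rlang::abort(sprintf("%s: probabilities must be non-negative", label))
    }
    if (abs(sum(p) - 1) > 1e-9) {
      rlang::abort(sprintf("%s: probabilities must sum to 1", label))
    }
    p
  }
  if (is.list(band_probabilities)) {
    band_probabilities <- purrr::imap(band_probabilities, function(p, nm) {
      check_probs(p, sprintf("band_probabilities$%s", nm))
    })
  } else {
    check_probs(band_probabilities, "band_probabilities")
  }
  structure(
    list(
      n_animals = as.integer(n_animals),
      band_probabilities = band_probabilities,
      within_band_placement = within_band_placement,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Baseline values from which synthetic deviations are expressed; generic
# round numbers per deviation kind (38 "degrees" for absolute schemes, 200
# "grams" for percent schemes) -- the scored band depends only on the
# deviation, not on the baseline magnitude.
synthetic_baseline <- function(bands) {
  if (bands$deviation_kind == "percent") 200 else 38
}

# Place a deviation inside band k (0-4) of a band scheme.
deviation_in_band <- function(band, bands, placement) {
  b <- bands$boundaries
  lower <- c(0, b)[band + 1L]
  upper <- c(b, 2 * b[4])[band + 1L]
  if (placement == "midpoint") {
    mid <- (lower + upper) / 2
    mid[band == 4L] <- 1.5 * b[4]
    mid
  } else {
    # uniform on (lower, upper]; top band on (b3, 2*b3]
    lower + stats::runif(length(band)) * (upper - lower)
  }
}

# Turn a deviation in band units back into a raw measurement.
value_from_deviation <- function(dev, baseline, bands) {
  delta <- if (bands$deviation_kind == "percent") dev / 100 * baseline else dev
  if (bands$direction == "decrease") baseline - delta else baseline + delta
}

#' Generate a synthetic cohort
#'
#' Draws, for each animal and criterion, a severity band from the spec's
#' band probabilities, places a deviation inside that band, and emits the
#' corresponding raw measurement together with a per-animal baseline.
#' Output is deterministic given the spec (including its seed).
#'
#' @param spec A [cohort_spec()].
#' @param scheme A [scheme_set()]; all of its criteria are simulated.
#' @param group_id,study_id,phase_id,timepoint Identifiers stamped on the
#'   generated records.
#' @return A list with `observations` and `baselines` tibbles in the same
#'   layout [score_observations()] reads, plus `true_bands`, the drawn
#'   band per animal x criterion (the simulation ground truth).
#' @examples
#' sp <- cohort_spec(5, c(0, 1, 0, 0, 0), seed = 42)
#' cohort <- generate_cohort(sp, rat_toxicity_scheme(), group_id = "low_dose")
#' cohort$observations
#' @export
generate_cohort <- function(spec, scheme, group_id = "group1",
                            study_id = "synthetic", phase_id = "phase1",
                            timepoint = "t1") {
  stopifnot(inherits(spec, "cohort_spec"), inherits(scheme, "scheme_set"))
  probs <- spec$band_probabilities
  if (!is.list(probs)) {
    probs <- purrr::map(scheme$criteria, function(cr) probs)
  } else {
    missing_cr <- setdiff(names(scheme$criteria), names(probs))
    if (length(missing_cr)) {
      rlang::abort(sprintf(
        "band_probabilities missing for criterion/criteria: %s",
        paste(missing_cr, collapse = ", ")
      ))
    }
  }
  animals <- sprintf("animal%03d", seq_len(spec$n_animals))
  out <- withr::with_seed(spec$seed, {
    purrr::imap(scheme$criteria, function(cr, nm) {
      band <- sample(0:4, spec$n_animals, replace = TRUE, prob = probs[[nm]])
      dev <- deviation_in_band(band, cr$bands, spec$within_band_placement)
      baseline <- synthetic_baseline(cr$bands)
      tibble::tibble(
        animal_id = animals,
        criterion = nm,
        band = band,
        value = value_from_deviation(dev, baseline, cr$bands),
        baseline_value = baseline
      )
    }) |>
      dplyr::bind_rows()
  })
  observations <- out |>
    dplyr::transmute(
      study_id = study_id, phase_id = phase_id, group_id = group_id,
      animal_id = .data$animal_id, timepoint = timepoint,
      criterion = .data$criterion, value = .data$value, status = "alive"
    )
  baselines <- out |>
    dplyr::distinct(.data$animal_id, .data$criterion, .data$baseline_value)
  true_bands <- out |>
    dplyr::select("animal_id", "criterion", "band")
  list(observations = observations, baselines = baselines,
       true_bands = true_bands)
}

#' The built-in worked example: two dose groups in a rat toxicity study
#'
#' Synthetic measurements constructed so that scoring them under
#' [rat_toxicity_scheme()] reproduces the published low-dose and high-dose
#' scoring matrices exactly: low-dose temperature scores (0, 1, 0, 1, 1)
#' and body-weight scores (1, 1, 1, 2, 1); high-dose temperature
#' (3, 3, 4, 2, 3) and body weight (3, 4, 4, 2, 3). Five rats per group,
#' one timepoint, baselines 38.0 degrees C and 200 g. Deviations sit at
#' band midpoints (1.5 x b3 for the top band).
#'
#' @return A list with `observations`, `baselines` and `scheme`.
#' @examples
#' fx <- rat_toxicity_example()
#' sc <- score_observations(fx$observations, fx$baselines, fx$scheme)
#' score_wide(sc)
#' @export
rat_toxicity_example <- function() {
  scheme <- rat_toxicity_scheme()
  fixture_bands <- tibble::tibble(
    group_id = rep(c("low_dose", "high_dose"), each = 10),
    animal_id = rep(rep(sprintf("rat%d", 1:5), times = 2), times = 2),
    criterion = rep(rep(c("temperature", "body_weight"), each = 5), times = 2),
    band = c(
      0L, 1L, 0L, 1L, 1L,  # low dose, temperature
      1L, 1L, 1L, 2L, 1L,  # low dose, body weight
      3L, 3L, 4L, 2L, 3L,  # high dose, temperature
      3L, 4L, 4L, 2L, 3L   # high dose, body weight
    )
  )
  # animal ids must be unique across groups in one study
  fixture_bands$animal_id <- paste(
    sub("_dose", "", fixture_bands$group_id), fixture_bands$animal_id,
    sep = "_"
  )
  rows <- fixture_bands |>
    dplyr::rowwise() |>
    dplyr::mutate(
      baseline_value = synthetic_baseline(
        scheme$criteria[[.data$criterion]]$bands
      ),
      value = value_from_deviation(
        deviation_in_band(.data$band,
                          scheme$criteria[[.data$criterion]]$bands,
                          "midpoint"),
        .data$baseline_value,
        scheme$criteria[[.data$criterion]]$bands
      )
    ) |>
    dplyr::ungroup()
  observations <- rows |>
    dplyr::transmute(
      study_id = "tox_example", phase_id = "phase1",
      group_id = .data$group_id, animal_id = .data$animal_id,
      timepoint = "day7", criterion = .data$criterion,
      value = .data$value, status = "alive"
    )
  baselines <- rows |>
    dplyr::distinct(.data$animal_id, .data$criterion, .data$baseline_value)
  list(observations = observations, baselines = baselines, scheme = scheme)
}
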