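# Helper: score matrix with given integer score columns for one group at
# one timepoint.
scores_from_columns <- function(cols, group = "g1", timepoint = "t1") {
  n <- length(cols[[1]])
  purrr::imap_dfr(cols, function(scores, criterion) {
    tibble::tibble(
      group_id = group, timepoint = timepoint,
      animal_id = sprintf("a%d", seq_len(n)),
      criterion = criterion, score = as.integer(scores),
      included = !is.na(scores), death_flag = FALSE
    )
  })
}

test_that("group criterion averages reproduce the worked-example figures", {
  cases <- list(
    list(scores = c(0, 1, 0, 1, 1), total = 3L, average = 0.6),
    list(scores = c(1, 1, 1, 2, 1), total = 6L, average = 1.2),
    list(scores = c(3, 3, 4, 2, 3), total = 15L, average = 3.0),
    list(scores = c(3, 4, 4, 2, 3), total = 16L, average = 3.2),
    list(scores = c(0, 0, 0, 0, 0), total = 0L, average = 0)
  )
  for (cs in cases) {
    avg <- group_criterion_average(scores_from_columns(list(c1 = cs$scores)))
    expect_equal(avg$total_score, cs$total)
    expect_equal(avg$n_animals, 5L)
    expect_equal(avg$average, cs$average)
  }
  all_na <- scores_from_columns(list(c1 = rep(NA_integer_, 3)))
  expect_error(group_criterion_average(all_na), "no scored animals")
})

test_that("overall impact score is N x mean of criterion averages", {
  expect_equal(overall_impact_score(c(0.6, 1.2), 5), 4.5)
  expect_equal(overall_impact_score(c(3, 3.2), 5), 15.5)
  expect_equal(overall_impact_score(c(0, 0), 7), 0)
  expect_error(overall_impact_score(numeric(0), 5), "at least one")
  expect_error(overall_impact_score(c(1, 2), 0), "at least 1")
})

test_that("per-animal average is the overall score spread over animals", {
  expect_equal(per_animal_average(4.5, 5), 0.9)
  expect_equal(per_animal_average(15.5, 5), 3.1)
  expect_equal(per_animal_average(0, 9), 0)
  expect_error(per_animal_average(4.5, 0), "at least 1")
})

test_that("individual animal scores are per-animal criterion means", {
  sc <- scores_from_columns(list(temp = c(4, 0, 1), weight = c(4, 0, 2)))
  ind <- individual_animal_score(sc)
  ind <- ind[order(ind$animal_id), ]
  expect_equal(ind$individual_score, c(4, 0, 1.5))
  all_na <- scores_from_columns(list(c1 = c(1, NA), c2 = c(1, NA)))
  expect_error(individual_animal_score(all_na), "no scored criteria")
})

test_that("per-animal average equals the unweighted mean of criterion averages", {
  withr::local_seed(2024)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    k <- sample(1:5, 1)
    cols <- purrr::map(seq_len(k), ~ sample(0:4, n, replace = TRUE))
    names(cols) <- sprintf("c%d", seq_len(k))
    sc <- scores_from_columns(cols)
    avg <- group_criterion_average(sc)
    overall <- overall_impact_score(avg$average, n)
    expect_equal(per_animal_average(overall, n), mean(avg$average),
                 tolerance = 1e-12)
    # consistency on complete matrices: mean of individual scores matches
    ind <- individual_animal_score(sc)
    expect_equal(mean(ind$individual_score), per_animal_average(overall, n),
                 tolerance = 1e-12)
    # bounds
    expect_gte(overall, 0); expect_lte(overall, 4 * n)
    expect_true(all(ind$individual_score >= 0 & ind$individual_score <= 4))
  }
})

test_that("aggregation is invariant to animal ordering", {
  withr::local_seed(11)
  cols <- list(temp = sample(0:4, 8, TRUE), weight = sample(0:4, 8, TRUE))
  sc <- scores_from_columns(cols)
  shuffled <- sc[sample(nrow(sc)), ]
  ga1 <- aggregate_scores(sc)
  ga2 <- aggregate_scores(shuffled)
  expect_equal(ga1$overall_score, ga2$overall_score)
  expect_equal(ga1$per_animal_average, ga2$per_animal_average)
  expect_equal(
    dplyr::arrange(ga1$criterion_averages[[1]], criterion),
    dplyr::arrange(ga2$criterion_averages[[1]], criterion)
  )
})

test_that("aggregate_scores assembles the full worked example", {
  fx <- rat_toxicity_example()
  ga <- aggregate_scores(
    score_observations(fx$observations, fx$baselines, fx$scheme)
  )
  low <- ga[ga$group_id == "low_dose", ]
  high <- ga[ga$group_id == "high_dose", ]
  expect_equal(low$overall_score, 4.5)
  expect_equal(low$per_animal_average, 0.9)
  expect_equal(high$overall_score, 15.5)
  expect_equal(high$per_animal_average, 3.1)
  expect_equal(low$n_animals, 5L)
  expect_equal(low$n_criteria, 2L)
})

test_that("incomplete matrices use per-criterion and per-animal denominators", {
  cols <- list(temp = c(2, NA, 4), weight = c(0, 2, 2))
  sc <- scores_from_columns(cols)
  avg <- group_criterion_average(sc)
  expect_equal(avg$n_animals[avg$criterion == "temp"], 2L)
  expect_equal(avg$average[avg$criterion == "temp"], 3)
  ind <- individual_animal_score(sc)
  expect_equal(ind$individual_score[ind$animal_id == "a2"], 2)
  expect_equal(ind$n_criteria[ind$animal_id == "a2"], 1L)
})
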