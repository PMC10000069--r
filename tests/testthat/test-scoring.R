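temp_bands <- band_scheme(c(0.2, 1, 2, 3), "absolute", "increase")
weight_bands <- band_scheme(c(5, 10, 20, 30), "percent", "decrease")

test_that("deviation computes directed absolute and percent changes", {
  expect_equal(deviation(39.0, 38.0, temp_bands), 1.0)
  expect_equal(deviation(190, 200, weight_bands), 5.0)
  # opposite-direction excursion maps to zero, with a warning
  expect_warning(d <- deviation(37.5, 38.0, temp_bands), "opposite")
  expect_equal(d, 0)
  either <- band_scheme(c(0.2, 1, 2, 3), "absolute", "either")
  expect_equal(deviation(37.5, 38.0, either), 0.5)
  expect_error(deviation(190, 0, weight_bands), "positive baseline")
  expect_error(deviation(NaN, 38, temp_bands), "finite")
})

test_that("assign_band follows the right-closed band convention", {
  expect_equal(assign_band(0.5, temp_bands), 1L)
  expect_equal(assign_band(0, temp_bands), 0L)
  expect_equal(assign_band(25, weight_bands), 3L)
  # boundaries belong to the lower band: 0.2 is normal, 1.0 is mild
  expect_equal(assign_band(c(0.2, 1, 2, 3), temp_bands), 0:3)
  expect_equal(assign_band(3.0001, temp_bands), 4L)
  expect_error(assign_band(-0.1, temp_bands), "non-negative")
  expect_equal(assign_band(NA_real_, temp_bands), NA_integer_)
})

test_that("assign_band agrees with a brute-force interval scan on random cases", {
  withr::local_seed(1234)
  for (rep in 1:20) {
    bs <- random_band_scheme()
    dev <- c(0, bs$boundaries,                     # exact boundary hits
             runif(500, 0, 2 * max(bs$boundaries)))
    expect_equal(as.numeric(assign_band(dev, bs)),
                 oracle_band(dev, bs$boundaries))
  }
})

test_that("assign_band is non-decreasing in deviation", {
  withr::local_seed(99)
  for (rep in 1:10) {
    bs <- random_band_scheme()
    dev <- sort(runif(200, 0, 2 * max(bs$boundaries)))
    expect_true(all(diff(assign_band(dev, bs)) >= 0))
  }
})

test_that("scoring value v under increase equals scoring 2b - v under decrease", {
  withr::local_seed(7)
  inc <- band_scheme(c(0.2, 1, 2, 3), "absolute", "increase")
  dec <- band_scheme(c(0.2, 1, 2, 3), "absolute", "decrease")
  b <- 38
  v <- b + runif(100, 0, 5)  # increases only, to avoid the one-sided warning
  mirrored <- 2 * b - v
  expect_equal(deviation(v, b, inc), deviation(mirrored, b, dec))
})

test_that("score_observations reproduces the low-dose scoring matrix", {
  fx <- rat_toxicity_example()
  sc <- score_observations(fx$observations, fx$baselines, fx$scheme)
  wide <- score_wide(sc)
  low <- wide[wide$group_id == "low_dose", ]
  low <- low[order(low$animal_id), ]
  expect_equal(low$temperature, c(0L, 1L, 0L, 1L, 1L))
  expect_equal(low$body_weight, c(1L, 1L, 1L, 2L, 1L))
})

test_that("dead animals score 4 everywhere from death onward, regardless of values", {
  obs <- dplyr::bind_rows(
    make_obs(c(r1 = 38.1, r2 = 38.1), "temperature", timepoint = "d1"),
    make_obs(c(r1 = 190, r2 = 190), "body_weight", timepoint = "d1"),
    # r2 dies at d2 with no measurements; r1 measured normally
    make_obs(c(r1 = 38.1), "temperature", timepoint = "d2"),
    make_obs(c(r1 = 190), "body_weight", timepoint = "d2"),
    tibble::tibble(study_id = "s1", phase_id = "p1", group_id = "g1",
                   animal_id = "r2", timepoint = "d2",
                   criterion = "temperature", value = NA_real_,
                   status = "dead")
  )
  bl <- dplyr::bind_rows(
    make_baselines(c("r1", "r2"), "temperature", 38),
    make_baselines(c("r1", "r2"), "body_weight", 200)
  )
  sc <- score_observations(obs, bl, rat_toxicity_scheme())
  r2_d2 <- sc[sc$animal_id == "r2" & sc$timepoint == "d2", ]
  expect_equal(nrow(r2_d2), 2L)          # both criteria present
  expect_true(all(r2_d2$score == 4L))
  expect_true(all(r2_d2$death_flag))
  r1 <- sc[sc$animal_id == "r1", ]
  expect_false(any(r1$death_flag))
  expect_true(all(r1$score < 4L))
})

test_that("removed animals keep rows for audit but are excluded from statistics", {
  obs <- dplyr::bind_rows(
    make_obs(c(r1 = 38.1, r2 = 38.1), "temperature"),
    tibble::tibble(study_id = "s1", phase_id = "p1", group_id = "g1",
                   animal_id = "r3", timepoint = "t1",
                   criterion = "temperature", value = NA_real_,
                   status = "removed")
  )
  bl <- make_baselines(c("r1", "r2", "r3"), "temperature", 38)
  scheme <- scheme_set(list(criterion_scheme(
    "temperature", "C", c(0.2, 1, 2, 3), "absolute", "increase"
  )))
  sc <- score_observations(obs, bl, scheme)
  expect_true("r3" %in% sc$animal_id)            # audit trail retained
  expect_false(any(sc$included[sc$animal_id == "r3"]))
  avg <- group_criterion_average(sc)
  expect_equal(avg$n_animals, 2L)                 # denominator excludes r3
})

test_that("scoring rejects unknown criteria, duplicates and bad status", {
  scheme <- rat_toxicity_scheme()
  bl <- make_baselines("r1", "temperature", 38)
  obs <- make_obs(c(r1 = 38.5), "pulse")
  expect_error(score_observations(obs, bl, scheme), "unknown criterion")
  dup <- dplyr::bind_rows(make_obs(c(r1 = 38.5), "temperature"),
                          make_obs(c(r1 = 38.6), "temperature"))
  expect_error(score_observations(dup, bl, scheme), "duplicate")
  bad <- make_obs(c(r1 = 38.5), "temperature", status = "escaped")
  expect_error(score_observations(bad, bl, scheme), "unknown status")
  noBL <- make_obs(c(r9 = 38.5), "temperature")
  expect_error(score_observations(noBL, bl, scheme), "no baseline")
})

test_that("empty observation set yields an empty score matrix", {
  sc <- score_observations(
    tibble::tibble(study_id = character(), phase_id = character(),
                   group_id = character(), animal_id = character(),
                   timepoint = character(), criterion = character(),
                   value = double(), status = character()),
    tibble::tibble(animal_id = character(), criterion = character(),
                   baseline_value = double()),
    rat_toxicity_scheme()
  )
  expect_s3_class(sc, "score_matrix")
  expect_equal(nrow(sc), 0L)
})

test_that("control-mean baselines use the control group's timepoint mean", {
  scheme <- scheme_set(list(criterion_scheme(
    "temperature", "C", c(0.2, 1, 2, 3), "absolute", "increase",
    baseline_source = "control_mean"
  )))
  obs <- dplyr::bind_rows(
    make_obs(c(c1 = 37.9, c2 = 38.1), "temperature", group = "control"),
    make_obs(c(t1 = 39.0), "temperature", group = "treated")
  )
  # control animal c1 sits below the control mean: expected one-sided warning
  sc <- suppressWarnings(score_observations(obs, tibble::tibble(), scheme,
                                            control_group = "control"))
  treated <- sc[sc$animal_id == "t1", ]
  expect_equal(treated$deviation, 1.0)   # 39.0 - mean(37.9, 38.1)
  expect_equal(treated$score, 1L)
  expect_error(score_observations(obs, tibble::tibble(), scheme),
               "control_group")
})
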