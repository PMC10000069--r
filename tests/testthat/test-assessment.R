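test_that("severity-limit breach uses strict inequality with escalating actions", {
  scores <- tibble::tibble(
    animal_id = c("a1", "a2", "a3", "a4"),
    individual_score = c(4, 0.5, 1.0, 3.1)
  )
  v <- check_severity_limit(scores, "severe")
  expect_equal(v$breached, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(v$recommended_action[1], "humane_kill_candidate")
  expect_equal(v$recommended_action[4], "alert_licence_holder")
  # exactly at the limit is not a breach
  mild <- check_severity_limit(
    tibble::tibble(animal_id = "a1", individual_score = 1.0), "mild"
  )
  expect_false(mild$breached)
  expect_equal(mild$recommended_action, "none")
  expect_error(check_severity_limit(
    tibble::tibble(animal_id = "a", individual_score = 5), "mild"
  ), "\\[0, 4\\]")
})

test_that("classification outcomes are under / met / exceeded on strict comparison", {
  expect_equal(compare_classification(0.9, "mild")$outcome, "under")
  expect_equal(compare_classification(3.1, "severe")$outcome, "exceeded")
  expect_equal(compare_classification(1.0, "mild")$outcome, "met")
  expect_equal(compare_classification(0, "normal")$outcome, "met")
})

test_that("verdicts are monotone in score and in limit", {
  withr::local_seed(31)
  limits <- severity_levels()
  for (rep in 1:50) {
    s <- runif(1, 0, 4)
    lim <- sample(limits, 1)
    v <- check_severity_limit(
      tibble::tibble(animal_id = "a", individual_score = s), lim
    )$breached
    # raising the score never un-breaches
    s_up <- min(4, s + runif(1, 0, 4 - s))
    v_up <- check_severity_limit(
      tibble::tibble(animal_id = "a", individual_score = s_up), lim
    )$breached
    expect_true(v_up >= v)
    # raising the limit never creates a breach
    lim_up <- limits[min(5, severity_ordinal(lim) + 2)]
    v_lim <- check_severity_limit(
      tibble::tibble(animal_id = "a", individual_score = s), lim_up
    )$breached
    expect_true(v_lim <= v)
  }
})

test_that("cumulative severity: max mode dominates every phase; sum mode adds load", {
  ph <- tibble::tibble(
    phase_id = c("p1", "p2", "p3"),
    classification = c("mild", "severe", "mild"),
    per_animal_average = c(0.9, 3.1, 0.7)
  )
  cum <- cumulative_severity(ph)
  expect_equal(cum$classification, "severe")
  expect_true(all(severity_ordinal(cum$classification) >=
                    severity_ordinal(ph$classification)))
  single <- cumulative_severity(ph[1, ])
  expect_equal(single$classification, "mild")
  load <- cumulative_severity(ph[1:2, ], mode = "sum")
  expect_equal(load$cumulative_load, 4.0)
  expect_equal(load$classification, "severe")  # breakdown always present
  expect_equal(nrow(load$phases), 2L)
  expect_error(cumulative_severity(ph[0, ]), "at least one phase")
})

test_that("reuse eligibility compares prior severity against the policy threshold", {
  expect_equal(reuse_eligibility("severe"), "ineligible")
  expect_equal(reuse_eligibility("normal"), "eligible")
  expect_equal(reuse_eligibility("moderate"), "eligible")        # default policy
  expect_equal(reuse_eligibility("moderate", "mild"), "ineligible")
  expect_equal(
    reuse_eligibility(c("mild", "beyond_severe"), "moderate"),
    c("eligible", "ineligible")
  )
})

test_that("classify_average maps averages onto ceiling categories", {
  expect_equal(as.character(classify_average(c(0, 0.9, 1, 3, 3.1))),
               c("normal", "mild", "mild", "severe", "beyond_severe"))
})

test_that("full assessment of the worked example yields the published verdicts", {
  fx <- rat_toxicity_example()
  a <- assess_study(fx$observations, fx$baselines, fx$scheme)
  g <- glance(a)
  low <- g[g$group_id == "low_dose", ]
  high <- g[g$group_id == "high_dose", ]
  expect_equal(low$outcome, "under")        # 0.9 against mild
  expect_equal(high$outcome, "exceeded")    # 3.1 against severe
  # the animal scoring (4, 4) breaches the severe limit
  verdicts <- tidy(a)
  rat3 <- verdicts[verdicts$animal_id == "high_rat3", ]
  expect_equal(rat3$individual_score, 4)
  expect_true(rat3$breached)
  expect_equal(rat3$recommended_action, "humane_kill_candidate")
  expect_true(a$any_breach)
  expect_gte(high$n_breaching, 1L)
})

test_that("multi-phase studies report per-phase and cumulative severity", {
  fx <- rat_toxicity_example()
  obs2 <- fx$observations
  obs2$phase_id <- "phase2"
  obs2$timepoint <- "day14"
  # second phase: everyone recovered to baseline (normal)
  obs2$value[obs2$criterion == "temperature"] <- 38
  obs2$value[obs2$criterion == "body_weight"] <- 200
  a <- assess_study(dplyr::bind_rows(fx$observations, obs2),
                    fx$baselines, fx$scheme)
  expect_false(is.null(a$phases))
  per_phase <- a$phases$per_phase
  expect_equal(nrow(per_phase), 2L)
  expect_equal(
    per_phase$classification[per_phase$phase_id == "phase2"], "normal"
  )
  expect_equal(a$phases$cumulative$classification,
               as.character(classify_average(3.1)))
})

test_that("assessment methods return tidy tibbles and a plot", {
  fx <- rat_toxicity_example()
  a <- assess_study(fx$observations, fx$baselines, fx$scheme)
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("animal_id", "individual_score", "breached",
                    "recommended_action") %in% names(td)))
  g <- glance(a)
  expect_equal(nrow(g), 2L)
  p <- autoplot(a)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(a$scores), "ggplot")
})
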