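test_that("the same seed and configuration give bit-identical cohorts", {
  cfg <- simulation_config(seed = 123)
  a <- simulate_ipd(cfg)
  b <- simulate_ipd(cfg)
  expect_identical(a, b)
  c2 <- simulate_ipd(simulation_config(seed = 124))
  expect_false(identical(a$placebo_decline, c2$placebo_decline))
})

test_that("the noise-free limit recovers the proportional effect exactly", {
  cfg <- simulation_config(
    n_studies = 2, participants_per_study = 3,
    drug_labels = c("a", "b"),
    true_relative_effect = 0.9,
    study_slope_sd = 0, drug_slope_sd = 0, study_baseline_sd = 0,
    residual_sd = 0, within_subject_sd = 0,
    baseline_distribution = list(family = "fixed", value = 50),
    duplicate_placebo_fraction = 0, seed = 5)
  ipd <- simulate_ipd(cfg)
  expect_equal(nrow(ipd), 6L)
  expect_equal(ipd$placebo_decline, rep(50, 6))
  expect_equal(ipd$drug_decline, rep(5, 6))
  expect_equal(relative_effect(ipd$placebo_decline, ipd$drug_decline),
               rep(0.9, 6))
  expect_true(all(is.na(ipd$placebo_decline_repeat)))
})

test_that("a null effect leaves no systematic paired difference", {
  cfg <- simulation_config(
    n_studies = 50, participants_per_study = 200,
    drug_labels = rep("a", 50),
    true_relative_effect = 0,
    study_slope_sd = 0, drug_slope_sd = 0, study_baseline_sd = 0,
    residual_sd = 6, within_subject_sd = 6.23,
    duplicate_placebo_fraction = 0, seed = 77)
  ipd <- simulate_ipd(cfg)
  d <- ipd$placebo_decline - ipd$drug_decline
  mc_se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * mc_se)
})

test_that("the default cohort matches the published pool's structure", {
  ipd <- simulate_ipd(simulation_config())
  expect_equal(nrow(ipd), 187L)
  expect_equal(length(unique(ipd$study_id)), 14L)
  expect_equal(length(unique(ipd$drug)), 6L)
  med <- median(ipd$placebo_decline)
  expect_gte(med, 25)
  expect_lte(med, 37)
  # some studies report a second placebo test, others do not
  rep_by_study <- tapply(is.finite(ipd$placebo_decline_repeat),
                         ipd$study_id, any)
  expect_true(any(rep_by_study) && !all(rep_by_study))
})

test_that("the repeat placebo test recovers the within-subject SD", {
  cfg <- simulation_config(
    n_studies = 10, participants_per_study = 150,
    drug_labels = rep(c("a", "b"), 5),
    duplicate_placebo_fraction = 1, seed = 31)
  ipd <- simulate_ipd(cfg)
  expect_true(all(is.finite(ipd$placebo_decline_repeat)))
  est <- within_subject_sd(ipd$placebo_decline, ipd$placebo_decline_repeat)
  expect_lt(abs(est - 6.23) / 6.23, 0.10)
})

test_that("study-level aggregation matches hand values and the SD oracle", {
  base <- data.frame(study_id = "s1", drug = "a",
                     participant_id = c("p1", "p2"),
                     placebo_decline = c(30, 30),
                     drug_decline = c(20, 20))
  agg <- aggregate_to_study_level(base)
  expect_equal(agg$mean_diff, -10)
  expect_equal(agg$se_diff, 0)

  base$drug_decline <- c(0, 20)   # paired differences -30, -10
  agg <- aggregate_to_study_level(base)
  expect_equal(agg$mean_diff, -20)
  expect_equal(agg$se_diff, 10)

  ipd <- simulate_ipd(simulation_config(seed = 8))
  agg <- aggregate_to_study_level(ipd)
  for (sid in agg$study_id) {
    d <- with(ipd[ipd$study_id == sid, ], drug_decline - placebo_decline)
    expect_equal(agg$se_diff[agg$study_id == sid],
                 two_pass_sd(d) / sqrt(length(d)), tolerance = 1e-12)
  }

  solo <- base[1, ]
  expect_error(aggregate_to_study_level(solo), "fewer than 2")
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(simulation_config(true_relative_effect = 2),
               "true_relative_effect")
  expect_error(simulation_config(residual_sd = -1), "residual_sd")
  expect_error(simulation_config(baseline_distribution =
                                   list(family = "lognormal",
                                        meanlog = 3, sdlog = 0.5,
                                        lower = 5, upper = 99)),
               "baseline_distribution")
  expect_error(simulation_config(n_studies = 3,
                                 participants_per_study = c(5, 5),
                                 drug_labels = c("a", "b", "c")),
               "participants_per_study")
  expect_error(simulation_config(drug_labels = "a"), "drug_labels")
})
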