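test_that("participant-level effect arithmetic matches the worked example", {
  expect_equal(absolute_effect(70, 29), 41)
  expect_equal(absolute_effect(30, 30), 0)
  expect_equal(absolute_effect(20, 35), -15)
  expect_error(absolute_effect(NA, 10), "finite")

  expect_equal(relative_effect(70, 29), 41 / 70)
  expect_equal(relative_effect(70, 0), 1)
  expect_equal(relative_effect(70, 70), 0)
  expect_error(relative_effect(0, 10), "undefined")
})

test_that("relative effect equals 1 - drug/placebo for any nonzero decline", {
  set.seed(11)
  x <- runif(200, -50, 80)
  x <- x[x != 0]
  d <- runif(length(x), -20, 80)
  expect_equal(relative_effect(x, d), 1 - d / x)
})

test_that("strata counts follow the closed-open binning convention", {
  ipd <- data.frame(study_id = "s", drug = "a",
                    participant_id = sprintf("p%d", 1:7),
                    placebo_decline = c(5, 10, 19.99, 20, 35, 50, 60),
                    drug_decline = 0)
  st <- stratify_by_placebo_decline(ipd, bin_edges = c(10, 20, 50))
  # 5 falls below the first edge; 19.99 stays in [10,20); 20 moves up
  expect_equal(st$n, c(2L, 2L, 2L))
  # the final bin is closed at the observed maximum
  expect_equal(st$bin_high[3], 60)
  expect_equal(sum(st$n), 6L)
})

test_that("a degenerate stratum reproduces its ratio exactly", {
  ipd <- data.frame(study_id = "s", drug = "a",
                    participant_id = sprintf("p%d", 1:5),
                    placebo_decline = rep(20, 5),
                    drug_decline = rep(10, 5))
  st <- stratify_by_placebo_decline(ipd, bin_edges = 10)
  expect_equal(st$n, 5L)
  expect_equal(st$abs_point, 10)
  expect_equal(st$abs_se, 0)
  expect_equal(st$rel_point, 0.5)
})

test_that("ratio CIs are multiplicatively symmetric around the point", {
  ipd <- simulate_ipd(simulation_config(seed = 21))
  st <- stratify_by_placebo_decline(ipd)
  ok <- is.finite(st$rel_ci_low) & is.finite(st$rel_ci_high)
  expect_true(any(ok))
  expect_equal(st$rel_ci_high[ok] / st$rel_point[ok],
               st$rel_point[ok] / st$rel_ci_low[ok], tolerance = 1e-9)
})

test_that("stratified estimates are scale-equivariant", {
  ipd <- simulate_ipd(simulation_config(seed = 22))
  st1 <- stratify_by_placebo_decline(ipd, bin_edges = c(10, 30, 50))
  k <- 2.5
  ipd2 <- ipd
  ipd2$placebo_decline <- k * ipd$placebo_decline
  ipd2$drug_decline <- k * ipd$drug_decline
  st2 <- stratify_by_placebo_decline(ipd2, bin_edges = k * c(10, 30, 50))
  expect_equal(st2$n, st1$n)
  expect_equal(st2$rel_point, st1$rel_point, tolerance = 1e-12)
  expect_equal(st2$rel_ci_low, st1$rel_ci_low, tolerance = 1e-12)
  expect_equal(st2$abs_point, k * st1$abs_point, tolerance = 1e-12)
  expect_equal(st2$abs_se, k * st1$abs_se, tolerance = 1e-12)
})

test_that("through-origin quantile slopes match the check-loss oracle", {
  # constant ratio: every quantile equals it
  ipd <- data.frame(study_id = "s", drug = "a",
                    participant_id = sprintf("p%d", 1:4),
                    placebo_decline = c(10, 20, 40, 55),
                    drug_decline = 0.2 * c(10, 20, 40, 55))
  q <- quantile_relative_effect(ipd, c(0.25, 0.5, 0.75))
  expect_equal(unname(q), rep(0.8, 3))

  # hand instance: candidate ratios 0.2, 0.8, 0.9 with weights 10, 20, 40;
  # the q = 0.5 check loss is minimized at 0.9
  x <- c(10, 20, 40); a <- c(2, 16, 36)
  expect_equal(checkloss_origin_quantile(x, a, 0.5), 0.9)
  ipd <- data.frame(study_id = "s", drug = "a",
                    participant_id = c("p1", "p2", "p3"),
                    placebo_decline = x, drug_decline = x - a)
  expect_equal(unname(quantile_relative_effect(ipd, 0.5)), 0.9)

  # random small instances against the brute-force minimizer
  set.seed(303)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    x <- runif(n, 5, 70)
    a <- runif(n, -15, 70)
    ipd <- data.frame(study_id = "s", drug = "a",
                      participant_id = sprintf("p%d", seq_len(n)),
                      placebo_decline = x, drug_decline = x - a)
    for (qq in c(0.25, 0.5, 0.75)) {
      got <- unname(quantile_relative_effect(ipd, qq,
                                             min_placebo_decline = 1))
      expect_equal(got, checkloss_origin_quantile(x, a, qq),
                   tolerance = 1e-12)
    }
  }

  expect_error(quantile_relative_effect(ipd, 0.5,
                                        min_placebo_decline = 1000),
               "no participants")
})

test_that("skewness matches the moment oracle and handles edge cases", {
  expect_equal(skewness(c(-1, 0, 1)), 0)
  x <- c(0, 0, 0, 1)
  expect_gt(skewness(x), 0)
  expect_equal(skewness(x), skew_oracle(x), tolerance = 1e-12)
  set.seed(12)
  y <- rlnorm(100)
  expect_equal(skewness(y), skew_oracle(y), tolerance = 1e-12)
  n <- length(y)
  expect_equal(skewness(y, adjusted = TRUE),
               skew_oracle(y) * sqrt(n * (n - 1)) / (n - 2))
  expect_error(skewness(c(1, 2)), "at least 3")
  expect_error(skewness(rep(4, 10)), "zero variance")
})
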