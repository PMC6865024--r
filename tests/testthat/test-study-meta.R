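make_studies <- function(mean_placebo, mean_diff, se = 2, n = 12,
                         drug = NULL) {
  k <- length(mean_placebo)
  if (is.null(drug)) drug <- rep(c("a", "b", "c"), length.out = k)
  data.frame(study_id = sprintf("s%02d", seq_len(k)), drug = drug,
             n = rep(n, length.out = k),
             mean_placebo_decline = mean_placebo,
             mean_drug_decline = mean_placebo + mean_diff,
             mean_diff = mean_diff, se_diff = rep(se, length.out = k),
             stringsAsFactors = FALSE)
}

test_that("study-level models recover a uniform absolute effect exactly", {
  st <- make_studies(mean_placebo = c(20, 30, 40, 50, 60),
                     mean_diff = rep(-20, 5))
  res <- suppressWarnings(fit_study_level_models(st))
  f <- res$fits$intercept_only
  expect_equal(f$alpha, -20, tolerance = 1e-6)
  expect_lt(f$residual_sd, 1e-4)
  expect_error(fit_study_level_models(st[1:2, ]), "at least 3")
})

test_that("a single drug level drops the random term with a warning", {
  st <- make_studies(mean_placebo = c(20, 35, 50, 65),
                     mean_diff = c(-18, -31, -46, -58),
                     drug = rep("a", 4))
  w <- capture_warnings(res <- fit_study_level_models(st))
  expect_match(w, "fewer than 2 levels", all = FALSE)
  expect_equal(res$fits$slope_only$engine, "lm")
})

test_that("study-level slope recovery works on aggregated synthetic data", {
  covered <- 0L
  for (seed in 201:210) {
    ipd <- simulate_ipd(simulation_config(seed = seed))
    st <- aggregate_to_study_level(ipd)
    res <- suppressWarnings(fit_study_level_models(st))
    b <- res$fits$slope_only
    if (b$beta_ci[1] <= -0.90 && -0.90 <= b$beta_ci[2])
      covered <- covered + 1L
  }
  expect_gte(covered, 8L)
})

test_that("normalization converts summaries to the relative scale", {
  st <- make_studies(50, -25, se = 2)
  est <- to_relative_by_normalization(st)
  expect_equal(est$estimate, 0.5)
  expect_equal(est$se, 0.04)
  expect_equal(attr(est, "scale"), "relative_proportion")

  expect_equal(to_relative_by_normalization(make_studies(50, 0))$estimate, 0)
  expect_equal(to_relative_by_normalization(make_studies(50, -50))$estimate, 1)
  expect_error(to_relative_by_normalization(make_studies(-5, 2)),
               "positive mean placebo decline")
})

test_that("per-study slopes match hand arithmetic", {
  x <- c(10, 25, 40, 55)
  ipd <- data.frame(study_id = "s1", drug = "a",
                    participant_id = sprintf("p%d", 1:4),
                    placebo_decline = x, drug_decline = 0.1 * x)
  est <- suppressWarnings(to_relative_by_slope(ipd))  # Y = -0.9 X exactly
  expect_equal(est$estimate, 0.9, tolerance = 1e-12)
  expect_equal(est$se, 0, tolerance = 1e-9)

  # hand instance: slope = sum(XY)/sum(X^2) = -1930/2100
  x <- c(10, 20, 40); y <- c(-5, -14, -40)
  ipd <- data.frame(study_id = "s1", drug = "a",
                    participant_id = c("p1", "p2", "p3"),
                    placebo_decline = x, drug_decline = x + y)
  est <- to_relative_by_slope(ipd)
  expect_equal(est$estimate, 1930 / 2100, tolerance = 1e-12)

  expect_error(to_relative_by_slope(ipd[1:2, ]), "fewer than 3")
})

test_that("DerSimonian-Laird pooling matches the direct-formula oracle", {
  # fixed hand instance
  est <- data.frame(estimate = c(1, 2, 3), se = c(0.5, 0.5, 0.5))
  m <- pool_random_effects(est, scale = "absolute_pp")
  o <- dl_oracle(est$estimate, est$se)
  expect_equal(m$pooled, o$pooled, tolerance = 1e-9)
  expect_equal(m$q, o$q, tolerance = 1e-9)
  expect_equal(m$tau2, o$tau2, tolerance = 1e-9)
  expect_equal(m$i2, o$i2, tolerance = 1e-9)

  # random sets of 3-10 studies
  set.seed(606)
  for (i in 1:30) {
    k <- sample(3:10, 1)
    theta <- rnorm(k, 0.8, 0.4)
    se <- runif(k, 0.05, 0.5)
    m <- pool_random_effects(data.frame(estimate = theta, se = se),
                             scale = "relative_proportion")
    o <- dl_oracle(theta, se)
    expect_equal(m$pooled, o$pooled, tolerance = 1e-9)
    expect_equal(m$se, o$se, tolerance = 1e-9)
    expect_equal(m$tau2, o$tau2, tolerance = 1e-9)
    # pooled estimate always lies inside the range of the inputs
    expect_gte(m$pooled, min(theta) - 1e-12)
    expect_lte(m$pooled, max(theta) + 1e-12)
  }
})

test_that("pooling agrees with metafor's DL implementation", {
  skip_if_not_installed("metafor")
  set.seed(77)
  theta <- rnorm(8, 0.8, 0.3)
  se <- runif(8, 0.05, 0.4)
  m <- pool_random_effects(data.frame(estimate = theta, se = se),
                           scale = "relative_proportion")
  r <- metafor::rma(yi = theta, sei = se, method = "DL")
  expect_equal(m$pooled, as.numeric(r$beta), tolerance = 1e-8)
  expect_equal(m$se, r$se, tolerance = 1e-8)
  expect_equal(m$tau2, r$tau2, tolerance = 1e-8)
  expect_equal(m$q, r$QE, tolerance = 1e-8)
})

test_that("degenerate and invalid pooling inputs are handled", {
  expect_error(pool_random_effects(data.frame(estimate = 1, se = 0.2),
                                   scale = "absolute_pp"),
               "at least 2")
  two <- data.frame(estimate = c(0.8, 0.8), se = c(0.1, 0.1))
  m <- pool_random_effects(two, scale = "relative_proportion")
  expect_equal(m$pooled, 0.8)
  expect_equal(m$se, 0.1 / sqrt(2))
  expect_equal(m$q, 0)
  expect_equal(m$i2, 0)

  expect_error(pool_random_effects(data.frame(estimate = c(1, 2),
                                              se = c(0, 0.1)),
                                   scale = "absolute_pp"),
               "continuity")
  mixed <- data.frame(estimate = c(1, 0.5), se = c(0.1, 0.1),
                      scale = c("absolute_pp", "relative_proportion"))
  expect_error(pool_random_effects(mixed), "mix scales")
})

test_that("heterogeneity statistics follow the I2 identities", {
  expect_equal(heterogeneity(13, 14)$i2, 0)
  expect_equal(heterogeneity(26, 14)$i2, 0.5)
  expect_equal(heterogeneity(68.4, 14)$i2, (68.4 - 13) / 68.4)
  expect_equal(heterogeneity(0, 5)$i2, 0)
  expect_equal(heterogeneity(10, 6)$p_value,
               pchisq(10, 5, lower.tail = FALSE))
  expect_error(heterogeneity(-1, 5), "non-negative")
  expect_error(heterogeneity(3, 1), "k >= 2")
})

test_that("normalization commutes with pooling under a shared placebo mean", {
  st <- make_studies(mean_placebo = rep(40, 6),
                     mean_diff = c(-30, -25, -35, -28, -32, -27),
                     se = c(2, 3, 2.5, 2, 4, 3))
  m_abs <- pool_random_effects(to_absolute_effect(st))
  m_rel <- pool_random_effects(to_relative_by_normalization(st))
  expect_equal(m_rel$pooled, m_abs$pooled / 40, tolerance = 1e-12)
  expect_equal(m_rel$q, m_abs$q, tolerance = 1e-9)
})

test_that("the slope route is more precise than normalization on
           proportional data", {
  ipd <- simulate_ipd(simulation_config(seed = 505))
  st <- aggregate_to_study_level(ipd)
  m_norm <- pool_random_effects(to_relative_by_normalization(st))
  m_slope <- pool_random_effects(to_relative_by_slope(ipd))
  expect_gt(m_slope$z, m_norm$z)
})
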