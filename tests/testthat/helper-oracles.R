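# Independent oracles, coded directly from first principles so they share no
# code path with the package implementation.

# two-pass standard deviation: mean first, then squared deviations
two_pass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# DerSimonian-Laird pooling by direct formula evaluation
dl_oracle <- function(theta, se) {
  w <- se^-2
  tf <- sum(w * theta) / sum(w)
  q <- sum(w * (theta - tf)^2)
  k <- length(theta)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  list(pooled = sum(ws * theta) / sum(ws),
       se = sqrt(1 / sum(ws)),
       q = q, tau2 = tau2,
       i2 = if (q > 0) max(0, (q - (k - 1)) / q) else 0)
}

# through-origin quantile regression by brute force over the candidate
# breakpoints (the per-point ratios), minimizing the check loss
checkloss_origin_quantile <- function(x, a, q) {
  loss <- function(b) {
    u <- a - b * x
    sum(u * (q - (u < 0)))
  }
  cand <- sort(a / x)
  cand[which.min(vapply(cand, loss, numeric(1)))]
}

# third standardized moment, written out longhand
skew_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m3 / m2^(3 / 2)
}

# small proportional cohort used across model tests
make_proportional_ipd <- function(n_studies = 6, n_per = 12, rho = 0.9,
                                  noise = 0.5, seed = 404) {
  set.seed(seed)
  x <- runif(n_studies * n_per, 10, 70)
  data.frame(
    study_id = rep(sprintf("s%02d", seq_len(n_studies)), each = n_per),
    drug = rep(rep(c("drugA", "drugB", "drugC"),
                   length.out = n_studies), each = n_per),
    participant_id = sprintf("p%03d", seq_len(n_studies * n_per)),
    placebo_decline = x,
    drug_decline = x * (1 - rho) + rnorm(length(x), 0, noise),
    placebo_decline_repeat = NA_real_,
    stringsAsFactors = FALSE)
}
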