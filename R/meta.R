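#' Per-study absolute effects for meta-analysis
#'
#' Converts study summaries to per-study absolute effect estimates (pp of
#' decline prevented, so a helpful drug gives positive values): point
#' `-mean_diff`, SE `se_diff`, with a normal-theory CI.
#'
#' @param studies Study-summary data.frame (see
#'   [aggregate_to_study_level()]).
#' @param confidence CI level. Default 0.95.
#' @return A data.frame with columns `study_id`, `n`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, carrying attribute `scale = "absolute_pp"`.
#' @export
to_absolute_effect <- function(studies, confidence = 0.95) {
  make_estimates(studies$study_id, studies$n,
                 est = -studies$mean_diff, se = studies$se_diff,
                 scale = "absolute_pp", confidence = confidence)
}

#' Per-study relative effects by normalization
#'
#' The simple transformation that makes relative-scale pooling possible with
#' summary data only: the absolute mean effect and its SE are divided by the
#' study's mean placebo decline. Full prevention maps to 1, no effect to 0.
#'
#' @inheritParams to_absolute_effect
#' @return A data.frame like [to_absolute_effect()] but with attribute
#'   `scale = "relative_proportion"`.
#' @export
to_relative_by_normalization <- function(studies, confidence = 0.95) {
  if (any(studies$mean_placebo_decline <= 0))
    stop("normalization requires a positive mean placebo decline in ",
         "every study", call. = FALSE)
  make_estimates(studies$study_id, studies$n,
                 est = -studies$mean_diff / studies$mean_placebo_decline,
                 se = studies$se_diff / studies$mean_placebo_decline,
                 scale = "relative_proportion", confidence = confidence)
}

#' Per-study relative effects from regression slopes
#'
#' When IPD is available, each study's relative effect can instead be
#' estimated as the (through-origin, by default) least-squares slope of the
#' paired difference `Y = drug - placebo` on the placebo decline `X`,
#' reported as the prevented proportion `-slope` with its OLS standard
#' error. This usually gives smaller SEs than normalization.
#'
#' @param ipd IPD data.frame; each study needs at least 3 participants.
#' @param intercept Include an intercept in the per-study regression (the
#'   slope is still the reported effect). Default FALSE (through-origin,
#'   matching the slope-only model).
#' @param confidence CI level. Default 0.95.
#' @return A data.frame like [to_absolute_effect()] with attribute
#'   `scale = "relative_proportion"`.
#' @export
to_relative_by_slope <- function(ipd, intercept = FALSE,
                                 confidence = 0.95) {
  check_ipd(ipd)
  split_idx <- split(seq_len(nrow(ipd)), ipd$study_id)
  res <- lapply(names(split_idx), function(sid) {
    i <- split_idx[[sid]]
    if (length(i) < 3L)
      stop("study '", sid, "' has fewer than 3 participants", call. = FALSE)
    x <- ipd$placebo_decline[i]
    y <- ipd$drug_decline[i] - ipd$placebo_decline[i]
    if ((intercept && var(x) == 0) || (!intercept && all(x == 0)))
      stop("study '", sid, "' has a degenerate placebo-decline covariate",
           call. = FALSE)
    fit <- if (intercept) lm(y ~ x) else lm(y ~ 0 + x)
    sm <- summary(fit)$coefficients
    c(n = length(i), est = -sm["x", "Estimate"], se = sm["x", "Std. Error"])
  })
  m <- do.call(rbind, res)
  out <- make_estimates(names(split_idx), m[, "n"], m[, "est"], m[, "se"],
                        scale = "relative_proportion",
                        confidence = confidence)
  out[order(match(out$study_id, unique(ipd$study_id))), , drop = FALSE]
}

make_estimates <- function(study_id, n, est, se, scale, confidence) {
  zq <- qnorm(1 - (1 - confidence) / 2)
  out <- data.frame(study_id = as.character(study_id), n = as.integer(n),
                    estimate = unname(est), se = unname(se),
                    ci_low = unname(est - zq * se),
                    ci_high = unname(est + zq * se),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  attr(out, "confidence") <- confidence
  out
}

#' DerSimonian-Laird random-effects pooling
#'
#' Generic inverse-variance random-effects meta-analysis with the
#' moment-based DerSimonian-Laird estimate of the between-study variance:
#' fixed weights `w_j = 1/se_j^2` give Cochran's
#' `Q = sum w_j (theta_j - theta_fixed)^2`; then
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, random-effects
#' weights `w*_j = 1/(se_j^2 + tau2)`, pooled estimate
#' `sum(w* theta)/sum(w*)`, `se = 1/sqrt(sum w*)`, and z-based symmetric
#' confidence limits (no Knapp-Hartung adjustment). Heterogeneity is
#' reported as `I2 = max(0, (Q - df)/Q)`.
#'
#' @param estimates A data.frame of per-study estimates with columns
#'   `estimate` and `se` (and optionally `study_id`, `n`), as produced by
#'   [to_absolute_effect()], [to_relative_by_normalization()] or
#'   [to_relative_by_slope()]. All estimates must be on one scale; the scale
#'   is taken from the `scale` attribute (or the `scale` argument).
#' @param scale Overrides the scale attribute; one of `"absolute_pp"`,
#'   `"relative_proportion"`.
#' @param confidence CI level. Default 0.95.
#' @return An object of class `eib_meta`: `scale`, `k`, `pooled`, `se`,
#'   `z`, `p_value`, `ci`, `q`, `df`, `q_p_value`, `i2`, `tau2`, `weights`
#'   (normalized random-effects weights) and the per-study `studies` table.
#' @examples
#' est <- data.frame(estimate = c(1, 2, 3), se = c(0.5, 0.5, 0.5))
#' pool_random_effects(est, scale = "absolute_pp")
#' @export
pool_random_effects <- function(estimates, scale = NULL,
                                confidence = 0.95) {
  if ("scale" %in% names(estimates) &&
      length(unique(estimates$scale)) > 1L)
    stop("estimates mix scales; pool each scale separately", call. = FALSE)
  if (is.null(scale)) scale <- attr(estimates, "scale")
  if (is.null(scale) && "scale" %in% names(estimates))
    scale <- estimates$scale[1L]
  if (is.null(scale))
    stop("estimates carry no scale; supply scale = 'absolute_pp' or ",
         "'relative_proportion'", call. = FALSE)
  scale <- match.arg(scale, c("absolute_pp", "relative_proportion"))
  th <- estimates$estimate
  se <- estimates$se
  k <- length(th)
  if (k < 2L) stop("need at least 2 studies to pool", call. = FALSE)
  if (any(!is.finite(th)) || any(!is.finite(se)))
    stop("estimates and SEs must be finite", call. = FALSE)
  if (any(se == 0))
    stop("a study has SE 0; apply a continuity adjustment (e.g. a small ",
         "positive SE) before pooling", call. = FALSE)

  w <- 1 / se^2
  theta_f <- sum(w * th) / sum(w)
  q <- sum(w * (th - theta_f)^2)
  df <- k - 1L
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * th) / sum(wr)
  se_p <- 1 / sqrt(sum(wr))
  z <- pooled / se_p
  zq <- qnorm(1 - (1 - confidence) / 2)
  het <- heterogeneity(q, k)

  studies <- estimates
  studies$weight <- wr / sum(wr)
  structure(list(scale = scale, k = k,
                 pooled = pooled, se = se_p, z = z,
                 p_value = 2 * pnorm(-abs(z)),
                 ci = c(pooled - zq * se_p, pooled + zq * se_p),
                 q = q, df = df, q_p_value = het$p_value,
                 i2 = het$i2, tau2 = tau2,
                 weights = wr / sum(wr),
                 confidence = confidence,
                 studies = studies),
            class = "eib_meta")
}

#' Heterogeneity statistics from Cochran's Q
#'
#' `I2 = max(0, (Q - (k - 1)) / Q)` (0 when Q is 0) and the chi-square
#' p-value of Q on `k - 1` degrees of freedom. I2 above about 0.70 is
#' conventionally read as high heterogeneity.
#'
#' @param q Cochran's Q statistic (>= 0).
#' @param k Number of studies (>= 2).
#' @return A list with `i2` (proportion) and `p_value`.
#' @export
heterogeneity <- function(q, k) {
  if (q < 0) stop("Q must be non-negative", call. = FALSE)
  if (k < 2L) stop("need k >= 2", call. = FALSE)
  df <- k - 1
  list(i2 = if (q > 0) max(0, (q - df) / q) else 0,
       p_value = pchisq(q, df, lower.tail = FALSE))
}

#' @export
print.eib_meta <- function(x, ...) {
  rel <- x$scale == "relative_proportion"
  fmt <- function(v) if (rel) sprintf("%.0f%%", 100 * v)
                     else sprintf("%.1f pp", v)
  cat("Random-effects meta-analysis (DerSimonian-Laird,",
      if (rel) "relative scale)" else "absolute scale)", "\n")
  if (!is.null(x$studies$study_id)) {
    cat(sprintf("  %-12s %10s %18s %8s\n",
                "study", "estimate", "CI", "weight"))
    for (i in seq_len(x$k))
      cat(sprintf("  %-12s %10s %8s to %6s %7.1f%%\n",
                  x$studies$study_id[i], fmt(x$studies$estimate[i]),
                  fmt(x$studies$ci_low[i]), fmt(x$studies$ci_high[i]),
                  100 * x$studies$weight[i]))
  }
  cat(sprintf("  pooled: %s (%.0f%% CI %s to %s), Z = %.1f, p = %.2g\n",
              fmt(x$pooled), 100 * x$confidence, fmt(x$ci[1]), fmt(x$ci[2]),
              x$z, x$p_value))
  cat(sprintf("  heterogeneity: Q = %.1f on %d df (p = %.2g), I2 = %.0f%%, tau2 = %.3g\n",
              x$q, x$df, x$q_p_value, 100 * x$i2, x$tau2))
  invisible(x)
}
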