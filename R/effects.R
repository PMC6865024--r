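#' Absolute treatment effect for one participant
#'
#' The absolute effect is the percentage-point difference between the
#' exercise-induced FEV1 decline after placebo and after the active drug;
#' positive values mean the drug reduced the decline. A participant who fell
#' 70% after placebo and 29% after the drug has an absolute effect of 41 pp.
#'
#' @param placebo_decline,drug_decline Percent FEV1 declines (pp), positive
#'   when FEV1 fell. Vectorized.
#' @return `placebo_decline - drug_decline`, in pp.
#' @export
absolute_effect <- function(placebo_decline, drug_decline) {
  if (!all(is.finite(placebo_decline)) || !all(is.finite(drug_decline)))
    stop("declines must be finite", call. = FALSE)
  placebo_decline - drug_decline
}

#' Relative treatment effect for one participant
#'
#' The proportion of the untreated decline prevented by the drug:
#' `absolute_effect / placebo_decline`. 0 means no effect, 1 means the
#' decline was fully prevented; values below 0 (worsening) and above 1
#' (post-exercise FEV1 above the pre-exercise baseline) occur in real data.
#'
#' @inheritParams absolute_effect
#' @return The prevented proportion (dimensionless). Vectorized.
#' @export
relative_effect <- function(placebo_decline, drug_decline) {
  if (any(placebo_decline == 0))
    stop("relative effect is undefined when placebo_decline is 0; ",
         "exclude such participants from relative-scale summaries",
         call. = FALSE)
  absolute_effect(placebo_decline, drug_decline) / placebo_decline
}

#' Stratified absolute and relative effects by placebo-test decline
#'
#' Bins participants by their placebo-test decline and reports, per stratum,
#' the mean absolute effect with a t-interval on the paired differences and
#' the ratio-of-means relative effect `mean(absolute) / mean(placebo)` with a
#' confidence interval computed by the delta method on the log ratio and
#' exponentiated back, which makes the interval multiplicatively symmetric
#' around the point estimate.
#'
#' @param ipd IPD data.frame (see [simulate_ipd()]).
#' @param bin_edges Strictly increasing lower bin edges (pp). Records below
#'   the first edge are excluded; bins are closed-open `[low, high)` and the
#'   final bin extends to the maximum observed decline (closed at the top).
#' @param confidence Confidence level, default 0.95.
#' @param include_covariance Include the covariance between the mean absolute
#'   effect and the mean placebo decline in the delta-method variance
#'   (available here because IPD is in hand). Default TRUE; FALSE reproduces
#'   the summary-data variant that ignores it.
#' @return A data.frame of class `eib_strata`: one row per stratum with
#'   `bin_low`, `bin_high`, `n`, `mean_placebo_decline`, absolute-scale
#'   columns (`abs_*`, pp) and relative-scale columns (`rel_*`, proportions).
#'   Strata with n < 2 get `NA` SEs/CIs.
#' @export
stratify_by_placebo_decline <- function(ipd,
                                        bin_edges = c(10, 20, 30, 40, 50),
                                        confidence = 0.95,
                                        include_covariance = TRUE) {
  check_ipd(ipd)
  if (length(bin_edges) < 1L || is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing", call. = FALSE)
  x <- ipd$placebo_decline
  a <- absolute_effect(x, ipd$drug_decline)
  keep <- x >= bin_edges[1L]
  x <- x[keep]; a <- a[keep]
  top <- max(x)
  lows <- bin_edges
  highs <- c(bin_edges[-1L], max(top, bin_edges[length(bin_edges)]))
  alpha <- 1 - confidence

  rows <- lapply(seq_along(lows), function(j) {
    last <- j == length(lows)
    inb <- if (last) x >= lows[j] & x <= highs[j] else
      x >= lows[j] & x < highs[j]
    n <- sum(inb)
    xb <- x[inb]; ab <- a[inb]
    out <- data.frame(bin_low = lows[j], bin_high = highs[j], n = n,
                      mean_placebo_decline = NA_real_,
                      abs_point = NA_real_, abs_se = NA_real_,
                      abs_ci_low = NA_real_, abs_ci_high = NA_real_,
                      rel_point = NA_real_, rel_se = NA_real_,
                      rel_ci_low = NA_real_, rel_ci_high = NA_real_)
    if (n == 0L) return(out)
    out$mean_placebo_decline <- mean(xb)
    out$abs_point <- mean(ab)
    out$rel_point <- mean(ab) / mean(xb)
    if (n < 2L) return(out)          # SE/CI undefined, flagged as NA
    tq <- qt(1 - alpha / 2, df = n - 1)
    se_a <- sd(ab) / sqrt(n)
    out$abs_se <- se_a
    out$abs_ci_low <- out$abs_point - tq * se_a
    out$abs_ci_high <- out$abs_point + tq * se_a
    # delta method on log(mean(A)/mean(X))
    if (out$rel_point > 0 && mean(xb) > 0) {
      va <- var(ab) / n
      vx <- var(xb) / n
      cax <- if (include_covariance) cov(ab, xb) / n else 0
      vlog <- va / mean(ab)^2 + vx / mean(xb)^2 -
        2 * cax / (mean(ab) * mean(xb))
      if (vlog >= 0) {
        se_log <- sqrt(vlog)
        out$rel_se <- out$rel_point * se_log
        out$rel_ci_low <- out$rel_point * exp(-tq * se_log)
        out$rel_ci_high <- out$rel_point * exp(tq * se_log)
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "confidence") <- confidence
  class(res) <- c("eib_strata", "data.frame")
  res
}

#' @export
print.eib_strata <- function(x, digits = 3, ...) {
  cat("Stratified treatment effects by placebo-test FEV1 decline\n")
  cat(sprintf("  (%d strata, %d participants, %.0f%% CIs)\n\n",
              nrow(x), sum(x$n), 100 * attr(x, "confidence")))
  df <- data.frame(
    range = sprintf("%g-%g", x$bin_low, x$bin_high),
    n = x$n,
    mean_placebo = round(x$mean_placebo_decline, 1),
    absolute_pp = sprintf("%.1f (%.1f-%.1f)", x$abs_point,
                          x$abs_ci_low, x$abs_ci_high),
    relative = sprintf("%.2f (%.2f-%.2f)", x$rel_point,
                       x$rel_ci_low, x$rel_ci_high))
  print(df, row.names = FALSE)
  invisible(x)
}

# weighted lower quantile of values: smallest v with cumweight >= q * total
weighted_quantile <- function(values, weights, q) {
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w)
  tot <- cw[length(cw)]
  vapply(q, function(qq) v[which(cw >= qq * tot - 1e-12)[1L]], numeric(1))
}

#' Through-origin quantile-regression summaries of the relative effect
#'
#' Quantiles of the participant-level relative effect obtained as
#' through-origin quantile-regression slopes of the absolute effect on the
#' placebo decline. For a single covariate and positive declines the
#' check-loss minimizer over through-origin lines is the weighted quantile of
#' the per-participant ratios `absolute_effect / placebo_decline` with
#' weights `|placebo_decline|`, which is how it is computed here.
#'
#' @param ipd IPD data.frame.
#' @param quantiles Probabilities, default `c(0.25, 0.5, 0.75)`.
#' @param min_placebo_decline Only participants with a placebo decline of at
#'   least this value (pp) enter; must be > 0. Default 10, the conventional
#'   EIB threshold.
#' @return Named numeric vector of prevented proportions, one per quantile.
#' @export
quantile_relative_effect <- function(ipd,
                                     quantiles = c(0.25, 0.5, 0.75),
                                     min_placebo_decline = 10) {
  check_ipd(ipd)
  if (min_placebo_decline <= 0)
    stop("min_placebo_decline must be > 0", call. = FALSE)
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must lie strictly in (0, 1)", call. = FALSE)
  keep <- ipd$placebo_decline >= min_placebo_decline
  if (!any(keep))
    stop("no participants with placebo_decline >= ", min_placebo_decline,
         call. = FALSE)
  x <- ipd$placebo_decline[keep]
  r <- relative_effect(x, ipd$drug_decline[keep])
  setNames(weighted_quantile(r, abs(x), quantiles),
           sprintf("q%g", quantiles))
}

#' Sample skewness
#'
#' Third standardized central moment `m3 / m2^(3/2)` (the unadjusted moment
#' estimator); `adjusted = TRUE` applies the small-sample correction
#' `sqrt(n(n-1))/(n-2)`.
#'
#' @param values Numeric vector, at least 3 values with nonzero variance.
#' @param adjusted Apply the small-sample adjustment. Default FALSE.
#' @return The skewness (dimensionless).
#' @export
skewness <- function(values, adjusted = FALSE) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("skewness needs at least 3 values", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("skewness is undefined for zero variance", call. = FALSE)
  g1 <- mean((values - m)^3) / m2^1.5
  if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}
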