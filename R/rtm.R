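#' Within-subject SD from duplicate measurements
#'
#' Test-retest standard deviation of a single measurement estimated from
#' paired repeats: `SD(first - second) / sqrt(2)`.
#'
#' @param decline1,decline2 Paired measurements (pp), e.g. two placebo-test
#'   FEV1 declines of the same participants. At least 2 complete pairs.
#' @return Within-subject SD (pp).
#' @export
within_subject_sd <- function(decline1, decline2) {
  ok <- is.finite(decline1) & is.finite(decline2)
  if (sum(ok) < 2L)
    stop("need at least 2 complete pairs", call. = FALSE)
  sd(decline1[ok] - decline2[ok]) / sqrt(2)
}

#' Slope induced by regression to the mean in a null comparison
#'
#' Ordinary least-squares slope of the change between two null (e.g.
#' placebo-placebo) measurements on the first measurement:
#' `(decline2 - decline1) ~ decline1`. With pure test-retest noise its
#' expectation is `-s_w^2 / (s_b_true^2 + s_w^2)`, the classical attenuation
#' produced by regression to the mean.
#'
#' @inheritParams within_subject_sd
#' @return The OLS slope (dimensionless).
#' @export
rtm_observed_slope <- function(decline1, decline2) {
  ok <- is.finite(decline1) & is.finite(decline2)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  x <- decline1[ok]; y <- decline2[ok] - decline1[ok]
  if (var(x) == 0)
    stop("zero variance in the first measurement", call. = FALSE)
  unname(coef(lm(y ~ x))[["x"]])
}

#' Blomqvist correction of a change-on-baseline slope
#'
#' Corrects an observed slope of change on baseline for the attenuation
#' caused by measurement noise in the baseline: with
#' `r = s_w^2 / s_b^2` (within-subject over observed between-subject
#' variance), the corrected slope is `(observed_slope + r) / (1 - r)`.
#'
#' @param observed_slope The fitted slope of change on baseline.
#' @param s_w Within-subject SD (pp), see [within_subject_sd()].
#' @param s_b Observed between-subject SD of the baseline (pp).
#' @return The corrected (true) slope.
#' @examples
#' blomqvist_correct(-0.691, 6.23, 18.9)  # -0.653
#' @export
blomqvist_correct <- function(observed_slope, s_w, s_b) {
  if (s_w < 0 || s_b <= 0) stop("need s_w >= 0 and s_b > 0", call. = FALSE)
  r <- s_w^2 / s_b^2
  if (r >= 1)
    stop("correction undefined: s_w^2/s_b^2 = ", signif(r, 3), " >= 1",
         call. = FALSE)
  (observed_slope + r) / (1 - r)
}

#' Within-subject SD needed to produce a slope by regression to the mean
#'
#' Solves the attenuation model for the test-retest SD that would, by
#' itself, generate a given change-on-baseline slope when the true effect is
#' null. The true between-subject variance is taken as
#' `observed_between_sd^2 - observed_within_sd^2`, and the required SD
#' satisfies `s_w^2 = |target_slope| * s_b_true^2 / (1 - |target_slope|)`.
#'
#' @param target_slope Slope to be explained, `|target_slope| < 1`.
#' @param observed_between_sd Observed between-subject SD of the baseline
#'   (pp).
#' @param observed_within_sd Observed within-subject SD (pp); must be
#'   smaller than `observed_between_sd`.
#' @return The required within-subject SD (pp).
#' @export
required_within_sd <- function(target_slope, observed_between_sd,
                               observed_within_sd) {
  if (abs(target_slope) >= 1)
    stop("|target_slope| must be < 1", call. = FALSE)
  if (observed_within_sd >= observed_between_sd)
    stop("observed within-subject SD must be smaller than the ",
         "between-subject SD", call. = FALSE)
  sb_true2 <- observed_between_sd^2 - observed_within_sd^2
  sqrt(abs(target_slope) * sb_true2 / (1 - abs(target_slope)))
}

#' Regression-to-the-mean diagnostic for an IPD table
#'
#' Runs the three-part diagnostic on a cross-over IPD table: (1) the
#' null-comparison slope from the duplicate placebo tests, (2) the Blomqvist
#' correction of a supplied observed slope using the within-subject SD from
#' the duplicates and the between-subject SD over all participants' placebo
#' declines, and (3) the within-subject SD that would be required to produce
#' the observed slope by regression to the mean alone. The verdict is
#' `"negligible"` when the corrected and observed slopes differ by less than
#' `tolerance` (relative), i.e. regression to the mean cannot explain any
#' material part of the slope.
#'
#' @param ipd IPD data.frame with a `placebo_decline_repeat` column.
#' @param observed_slope The change-on-baseline slope to audit, typically
#'   the `beta` of the intercept-and-slope fit from [fit_ipd_model()].
#' @param tolerance Relative difference below which regression to the mean
#'   is called negligible. Default 0.10.
#' @return A list of class `eib_rtm`: `estimable`, `n_pairs`,
#'   `within_subject_sd`, `between_subject_sd`, `null_slope` (the
#'   duplicate-placebo slope, NA with < 3 pairs), `observed_slope`,
#'   `corrected_slope`, `required_within_sd`, `verdict`.
#' @export
rtm_diagnostic <- function(ipd, observed_slope, tolerance = 0.10) {
  check_ipd(ipd)
  rep_col <- ipd[["placebo_decline_repeat"]]
  ok <- !is.null(rep_col) && sum(is.finite(rep_col)) >= 2L
  s_b <- sd(ipd$placebo_decline)
  if (!ok) {
    return(structure(list(estimable = FALSE, n_pairs = 0L,
                          within_subject_sd = NA_real_,
                          between_subject_sd = s_b,
                          null_slope = NA_real_,
                          observed_slope = observed_slope,
                          corrected_slope = NA_real_,
                          required_within_sd = NA_real_,
                          verdict = "not estimable"),
                     class = "eib_rtm"))
  }
  has <- is.finite(rep_col)
  x1 <- ipd$placebo_decline[has]
  x2 <- rep_col[has]
  s_w <- within_subject_sd(x1, x2)
  null_slope <- if (sum(has) >= 3L && var(x1) > 0)
    rtm_observed_slope(x1, x2) else NA_real_
  corrected <- blomqvist_correct(observed_slope, s_w, s_b)
  req <- if (abs(observed_slope) < 1 && s_w < s_b)
    required_within_sd(observed_slope, s_b, s_w) else NA_real_
  rel_diff <- abs(corrected - observed_slope) /
    max(abs(observed_slope), .Machine$double.eps)
  structure(list(estimable = TRUE, n_pairs = sum(has),
                 within_subject_sd = s_w, between_subject_sd = s_b,
                 null_slope = null_slope,
                 observed_slope = observed_slope,
                 corrected_slope = corrected,
                 required_within_sd = req,
                 verdict = if (rel_diff < tolerance) "negligible"
                           else "non-negligible"),
            class = "eib_rtm")
}

#' @export
print.eib_rtm <- function(x, ...) {
  cat("Regression-to-the-mean diagnostic\n")
  if (!x$estimable) {
    cat("  not estimable: no duplicate placebo tests in the data\n")
    return(invisible(x))
  }
  cat(sprintf("  duplicate-placebo pairs: %d\n", x$n_pairs))
  cat(sprintf("  within-subject SD:  %.2f pp\n", x$within_subject_sd))
  cat(sprintf("  between-subject SD: %.2f pp\n", x$between_subject_sd))
  if (is.finite(x$null_slope))
    cat(sprintf("  null (placebo-placebo) slope: %.3f\n", x$null_slope))
  cat(sprintf("  observed slope %.3f -> Blomqvist-corrected %.3f\n",
              x$observed_slope, x$corrected_slope))
  if (is.finite(x$required_within_sd))
    cat(sprintf("  within-subject SD required to produce the slope: %.1f pp\n",
                x$required_within_sd))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
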