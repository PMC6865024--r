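MODEL_SPECS <- c("intercept_only", "intercept_and_slope", "slope_only")

# Shared fitting engine for the three nested specifications.
#
# data must hold columns y (response), x (covariate) and any grouping
# columns; groups are dropped (with a warning) when they have < 2 levels,
# and the model degrades to a plain (weighted) least-squares fit when no
# random term remains. Maximum likelihood throughout so log-likelihoods and
# AIC are comparable across fixed-effect structures.
fit_mixed <- function(data, spec, groups = character(0), weights = NULL,
                      confidence = 0.95) {
  spec <- match.arg(spec, MODEL_SPECS)
  has_int <- spec != "slope_only"
  has_slope <- spec != "intercept_only"

  usable <- character(0)
  for (g in groups) {
    if (length(unique(data[[g]])) >= 2L) usable <- c(usable, g)
    else warning("grouping variable '", g,
                 "' has fewer than 2 levels; random term dropped",
                 call. = FALSE)
  }

  fixed <- if (has_int && has_slope) "y ~ 1 + x"
           else if (has_int) "y ~ 1" else "y ~ 0 + x"
  ranef_terms <- character(0)
  for (g in usable) {
    if (has_int) ranef_terms <- c(ranef_terms, sprintf("(1 | %s)", g))
    if (has_slope) ranef_terms <- c(ranef_terms, sprintf("(0 + x | %s)", g))
  }

  data$.w <- if (is.null(weights)) rep(1, nrow(data)) else weights
  msgs <- character(0)
  if (length(ranef_terms)) {
    fml <- as.formula(paste(c(fixed, ranef_terms), collapse = " + "))
    fit <- withCallingHandlers(
      tryCatch(
        lme4::lmer(fml, data = data, REML = FALSE, weights = .w),
        error = function(e)
          stop("mixed-model fit failed for spec '", spec, "': ",
               conditionMessage(e), call. = FALSE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {          # lme4 signals singular fits this way
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    fe <- lme4::fixef(fit)
    # vcov can fail on fully degenerate (zero-residual) fits
    vc_fixed <- tryCatch(as.matrix(vcov(fit)),
                         error = function(e)
                           matrix(NA_real_, length(fe), length(fe)))
    fe_se <- setNames(sqrt(diag(vc_fixed)), names(fe))
    vc <- lme4::VarCorr(fit)
    vc_sd <- numeric(0)
    for (nm in names(vc)) {
      sds <- attr(vc[[nm]], "stddev")
      grp <- sub("\\.[0-9]+$", "", nm)
      names(sds) <- sprintf("%s:%s", grp,
                            ifelse(names(sds) == "(Intercept)",
                                   "intercept", names(sds)))
      vc_sd <- c(vc_sd, sds)
    }
    n_vc <- length(vc_sd)
    res_sd <- sigma(fit)
    resids <- residuals(fit)          # conditional: fixed + predicted ranef
    boundary <- lme4::isSingular(fit, tol = 1e-5)
    engine <- "lmer"
  } else {
    fml <- as.formula(fixed)
    fit <- lm(fml, data = data, weights = .w)
    fe <- coef(fit)
    fe_se <- sqrt(diag(vcov(fit)))
    vc_sd <- numeric(0)
    n_vc <- 0L
    res_sd <- sqrt(sum(data$.w * residuals(fit)^2) / nrow(data))  # ML sigma
    resids <- residuals(fit)
    boundary <- FALSE
    engine <- "lm"
  }

  ll <- as.numeric(logLik(fit))
  n_params <- length(fe) + n_vc + 1L
  zq <- qnorm(1 - (1 - confidence) / 2)
  get_term <- function(term) {
    if (!term %in% names(fe)) return(list(est = NULL, se = NULL, ci = NULL))
    est <- unname(fe[[term]]); se <- unname(fe_se[[term]])
    list(est = est, se = se, ci = c(est - zq * se, est + zq * se))
  }
  a <- get_term("(Intercept)")
  b <- get_term("x")

  structure(list(spec = spec,
                 alpha = a$est, alpha_se = a$se, alpha_ci = a$ci,
                 beta = b$est, beta_se = b$se, beta_ci = b$ci,
                 variance_components = vc_sd,
                 residual_sd = res_sd,
                 loglik = ll,
                 aic = 2 * n_params - 2 * ll,
                 n_params = n_params,
                 residuals = unname(resids),
                 n = nrow(data),
                 grouping = usable,
                 boundary = boundary,
                 messages = msgs,
                 engine = engine,
                 confidence = confidence,
                 data = list(y = data$y, x = data$x, w = data$.w),
                 model = fit),
            class = "eib_fit")
}

#' Fit one of the three nested IPD models
#'
#' The response is the signed paired difference
#' `Y = drug_decline - placebo_decline` and the covariate is the placebo
#' decline `X`, so the three specifications are `Y = alpha + e`
#' (intercept-only: one uniform absolute effect, `-alpha` pp),
#' `Y = alpha + beta * X + e`, and `Y = beta * X + e` (slope-only: one
#' proportional effect, `-beta` of the untreated decline prevented; a
#' helpful drug gives a negative `beta`). Fits are by maximum likelihood so
#' nested likelihood-ratio and AIC comparisons across specifications are
#' valid. Each fixed term carries independent random counterparts per study
#' and per drug: random intercepts for intercept terms, random slopes
#' (uncorrelated, no intercept) for slope terms.
#'
#' @param ipd IPD data.frame (see [simulate_ipd()], [read_ipd()]).
#' @param spec One of `"intercept_only"`, `"intercept_and_slope"`,
#'   `"slope_only"`.
#' @param confidence Level for Wald confidence intervals. Default 0.95.
#' @param grouping Clustering variables to use, any subset of
#'   `c("study", "drug")`; grouping factors with fewer than two observed
#'   levels are dropped with a warning (a single-study dataset degrades to
#'   ordinary least squares).
#' @return An object of class `eib_fit` with fixed estimates (`alpha`,
#'   `beta`) and Wald CIs, `variance_components` (SDs), `residual_sd`,
#'   `loglik`, `aic`, `n_params`, conditional `residuals`, and a `boundary`
#'   flag for singular variance components.
#' @examples
#' ipd <- simulate_ipd(simulation_config(seed = 7))
#' fit <- fit_ipd_model(ipd, "slope_only")
#' fit$beta          # close to -0.90
#' @export
fit_ipd_model <- function(ipd, spec = MODEL_SPECS, confidence = 0.95,
                          grouping = c("study", "drug")) {
  check_ipd(ipd)
  spec <- match.arg(spec)
  grouping <- match.arg(grouping, several.ok = TRUE)
  cols <- c(study = "study_id", drug = "drug")[grouping]
  d <- data.frame(y = ipd$drug_decline - ipd$placebo_decline,
                  x = ipd$placebo_decline)
  for (g in cols) d[[g]] <- factor(ipd[[g]])
  fit_mixed(d, spec, groups = unname(cols), confidence = confidence)
}

#' Fit the study-level weighted models
#'
#' Same three nested specifications as [fit_ipd_model()] but on study means:
#' the response is the mean paired difference, the covariate the mean
#' placebo decline, random terms are by drug only, and studies are weighted
#' by the square root of the number of participants (`"sqrt_n"`, the
#' default) or by the number of participants (`"n"`). Weights enter as case
#' weights (precision multipliers) in the likelihood.
#'
#' @param studies Study-summary data.frame (see [aggregate_to_study_level()]).
#' @param weight_scheme `"sqrt_n"` or `"n"`.
#' @param confidence Level for Wald CIs.
#' @return A list of class `eib_study_fits` with elements `fits` (named list
#'   of `eib_fit`), `comparisons` (`slope_added`: intercept+slope vs
#'   intercept-only; `intercept_removed`: slope-only vs intercept+slope) and
#'   `weight_scheme`.
#' @export
fit_study_level_models <- function(studies,
                                   weight_scheme = c("sqrt_n", "n"),
                                   confidence = 0.95) {
  weight_scheme <- match.arg(weight_scheme)
  if (nrow(studies) < 3L)
    stop("need at least 3 studies", call. = FALSE)
  w <- switch(weight_scheme, sqrt_n = sqrt(studies$n), n = studies$n)
  d <- data.frame(y = studies$mean_diff,
                  x = studies$mean_placebo_decline,
                  drug = factor(studies$drug))
  fits <- lapply(MODEL_SPECS, function(s)
    fit_mixed(d, s, groups = "drug", weights = w, confidence = confidence))
  names(fits) <- MODEL_SPECS
  comp <- list(
    slope_added = compare_fits(fits$intercept_only,
                               fits$intercept_and_slope),
    intercept_removed = compare_fits(fits$slope_only,
                                     fits$intercept_and_slope))
  structure(list(fits = fits, comparisons = comp,
                 weight_scheme = weight_scheme),
            class = "eib_study_fits")
}

#' Likelihood-ratio and AIC comparison of two nested fits
#'
#' Both fits must be maximum-likelihood fits on identical records, with the
#' restricted specification nested in the full one (intercept-only or
#' slope-only within intercept-and-slope). The statistic is
#' `chi2 = 2 * (loglik_full - loglik_restricted)` (clipped at zero), with
#' degrees of freedom equal to the parameter-count difference — 3 when a
#' fixed term and its two random counterparts (study, drug) enter together.
#'
#' @param restricted,full `eib_fit` objects.
#' @return An object of class `eib_comparison`: `chi2`, `df`, `p_value`,
#'   `delta_aic` (= AIC restricted minus AIC full; positive favours the full
#'   model).
#' @export
compare_fits <- function(restricted, full) {
  if (!inherits(restricted, "eib_fit") || !inherits(full, "eib_fit"))
    stop("both arguments must be eib_fit objects", call. = FALSE)
  same_data <- isTRUE(all.equal(restricted$data, full$data))
  if (!same_data)
    stop("fits were not computed on identical records", call. = FALSE)
  ok <- identical(restricted$spec, full$spec) ||
    (full$spec == "intercept_and_slope" &&
       restricted$spec %in% c("intercept_only", "slope_only"))
  if (!ok)
    stop("'", restricted$spec, "' is not nested in '", full$spec, "'",
         call. = FALSE)
  chi2 <- max(0, 2 * (full$loglik - restricted$loglik))
  df <- full$n_params - restricted$n_params
  p <- if (df > 0) pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  structure(list(chi2 = chi2, df = df, p_value = p,
                 delta_aic = restricted$aic - full$aic,
                 restricted = restricted$spec, full = full$spec),
            class = "eib_comparison")
}

#' Median absolute residual of a fit
#'
#' The median of the absolute conditional residuals (observed minus fixed
#' plus predicted random effects), in pp — a direct, scale-free measure of
#' how closely each model specification tracks individual participants.
#'
#' @param fit An `eib_fit`.
#' @return Median absolute residual (pp).
#' @export
median_abs_residual <- function(fit) {
  if (!inherits(fit, "eib_fit")) stop("not an eib_fit", call. = FALSE)
  median(abs(fit$residuals))
}

#' @export
print.eib_fit <- function(x, ...) {
  cat("Linear mixed-effects fit (ML):", x$spec, "\n")
  cat(sprintf("  n = %d, engine = %s%s\n", x$n, x$engine,
              if (x$boundary) " (variance component at boundary)" else ""))
  pct <- 100 * x$confidence
  if (!is.null(x$alpha))
    cat(sprintf("  absolute effect: %.1f pp reduction (%.0f%% CI %.1f to %.1f)\n",
                -x$alpha, pct, -x$alpha_ci[2], -x$alpha_ci[1]))
  if (!is.null(x$beta))
    cat(sprintf("  relative effect: %.0f%% of decline prevented (%.0f%% CI %.0f%% to %.0f%%)\n",
                -100 * x$beta, pct, -100 * x$beta_ci[2], -100 * x$beta_ci[1]))
  if (length(x$variance_components)) {
    cat("  random-effect SDs:\n")
    for (nm in names(x$variance_components))
      cat(sprintf("    %-22s %.3f\n", nm, x$variance_components[[nm]]))
  }
  cat(sprintf("  residual SD %.2f pp, logLik %.1f, AIC %.1f (%d parameters)\n",
              x$residual_sd, x$loglik, x$aic, x$n_params))
  invisible(x)
}

#' @export
print.eib_comparison <- function(x, ...) {
  cat(sprintf("LRT: %s vs %s\n", x$restricted, x$full))
  cat(sprintf("  chi2 = %.2f on %d df, p = %.3g, delta AIC = %.2f\n",
              x$chi2, x$df, x$p_value, x$delta_aic))
  invisible(x)
}

#' @export
print.eib_study_fits <- function(x, ...) {
  cat("Study-level weighted mixed models (weights:", x$weight_scheme, ")\n\n")
  for (f in x$fits) { print(f); cat("\n") }
  print(x$comparisons$slope_added)
  print(x$comparisons$intercept_removed)
  invisible(x)
}
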