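#' Fit a log-log time-response regression for one reference species
#'
#' Fits a Gaussian identity-link GLM of `ln(effect concentration)` on
#' `ln(exposure duration)` — equivalently ordinary least squares on the
#' log pairs — describing how the effect concentration of a
#' time-cumulative toxicant declines with exposure time.  The model
#' includes an intercept (the log effect concentration at day 1); the
#' slope is expected to be negative and a warning (not an error) is
#' raised otherwise.
#'
#' Diagnostics: `dsquared` is the explained deviance
#' `1 - deviance/null deviance` (equal to R-squared for this model);
#' `loocv_mse` is the mean squared leave-one-out prediction error on
#' the log scale, computed from the hat matrix.  Influential points
#' with Cook's distance above `cooks_threshold` (default 1.0) are
#' removed in at most one refit pass and recorded in
#' `removed_points`.
#'
#' @param series a data frame with columns `duration` (days) and
#'   `effect_concentration` (ug/L); optional `endpoint`, `source_id`.
#'   At least `min_points` rows after removals.
#' @param species_name,taxon_class labels carried into the model.
#' @param cooks_threshold Cook's distance above which a point is
#'   removed (set `Inf` to disable).
#' @param min_points minimum usable points (default 5, the
#'   conventional floor for a concentration-response regression).
#' @param inflection_threshold relative daily change used for the
#'   default inflection-day rule (see [inflection_day()]).
#' @return an object of class `time_response_model`; see
#'   [time_response_model()] for the fields.
#' @examples
#' s <- data.frame(duration = c(1, 2, 4, 8, 16),
#'                 effect_concentration = 100 / c(1, 2, 4, 8, 16))
#' m <- fit_time_response(s)
#' m$slope # -1
#' @export
fit_time_response <- function(series, species_name = "reference",
                              taxon_class = NA_character_,
                              cooks_threshold = 1.0, min_points = 5,
                              inflection_threshold = 0.05) {
  stopifnot(is.data.frame(series),
            all(c("duration", "effect_concentration") %in% names(series)))
  if (any(series$duration <= 0) || any(series$effect_concentration <= 0)) {
    stop("durations and effect concentrations must be positive", call. = FALSE)
  }
  if (nrow(series) < min_points) {
    stop("need at least ", min_points, " bioassay points; got ", nrow(series),
         call. = FALSE)
  }
  if (length(unique(series$duration)) < 2) {
    stop("all durations are equal; the time-response slope is not identifiable",
         call. = FALSE)
  }

  do_fit <- function(dat) {
    glm(log(effect_concentration) ~ log(duration), data = dat,
        family = gaussian())
  }
  fit <- do_fit(series)
  removed <- integer(0)
  # a numerically exact fit makes Cook's distance 0/0; nothing to remove
  cd <- if (fit$deviance > 1e-12 * max(1, fit$null.deviance)) {
    cooks.distance(fit)
  } else {
    rep(0, nrow(series))
  }
  infl <- which(cd > cooks_threshold)
  if (length(infl)) {
    if (nrow(series) - length(infl) < min_points) {
      stop("removing ", length(infl), " influential point(s) leaves fewer than ",
           min_points, " points", call. = FALSE)
    }
    removed <- as.integer(infl)
    series_used <- series[-infl, , drop = FALSE]
    if (length(unique(series_used$duration)) < 2) {
      stop("influential-point removal left all durations equal", call. = FALSE)
    }
    fit <- do_fit(series_used)
  } else {
    series_used <- series
  }

  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  h <- hatvalues(fit)
  r <- residuals(fit)
  null_dev <- fit$null.deviance
  dsq <- if (null_dev > 0) 1 - fit$deviance / null_dev else NA_real_
  model <- time_response_model(
    intercept = unname(cf[1]), slope = unname(cf[2]),
    se_intercept = unname(se[1]), se_slope = unname(se[2]),
    vcov = unname(vcov(fit)),
    residual_variance = fit$deviance / fit$df.residual,
    df_residual = fit$df.residual,
    dsquared = dsq,
    loocv_mse = mean((r / (1 - h))^2),
    n_points = nrow(series_used),
    removed_points = removed,
    fit_window_max_day = max(series_used$duration),
    species_name = species_name, taxon_class = taxon_class,
    inflection_threshold = inflection_threshold)
  if (model$slope >= 0) {
    warning("time-response slope is non-negative for ", species_name,
            "; toxicity does not accumulate with exposure time", call. = FALSE)
  }
  model
}

#' Construct a time-response model from known coefficients
#'
#' Builds the model object directly from an intercept and slope (on the
#' natural-log scale), e.g. coefficients transcribed from a published
#' regression table.  [fit_time_response()] uses this constructor
#' internally.
#'
#' @param intercept log effect concentration at day 1 (ln ug/L).
#' @param slope regression slope of ln(EC) on ln(duration); negative
#'   for time-cumulative toxicants.
#' @param se_intercept,se_slope standard errors (optional).
#' @param vcov 2x2 coefficient covariance matrix (needed for bootstrap
#'   prediction intervals; optional).
#' @param residual_variance,df_residual,dsquared,loocv_mse,n_points
#'   diagnostics (optional).
#' @param removed_points indices of influential points removed.
#' @param fit_window_max_day largest observed duration (days).
#' @param species_name,taxon_class labels.
#' @param inflection_threshold relative-change threshold for the
#'   default inflection rule.
#' @return an object of class `time_response_model`.
#' @export
time_response_model <- function(intercept, slope,
                                se_intercept = NA_real_, se_slope = NA_real_,
                                vcov = NULL, residual_variance = NA_real_,
                                df_residual = NA_real_,
                                dsquared = NA_real_, loocv_mse = NA_real_,
                                n_points = NA_integer_,
                                removed_points = integer(0),
                                fit_window_max_day = NA_real_,
                                species_name = "reference",
                                taxon_class = NA_character_,
                                inflection_threshold = 0.05) {
  m <- structure(
    list(species_name = species_name, taxon_class = taxon_class,
         intercept = intercept, slope = slope,
         se_intercept = se_intercept, se_slope = se_slope,
         vcov = vcov, residual_variance = residual_variance,
         df_residual = df_residual,
         dsquared = dsquared, loocv_mse = loocv_mse,
         n_points = n_points, removed_points = removed_points,
         fit_window_max_day = fit_window_max_day,
         inflection_day = NA_integer_),
    class = "time_response_model")
  if (slope < 0) {
    m$inflection_day <- inflection_day(m, threshold = inflection_threshold)
  }
  m
}

#' @export
print.time_response_model <- function(x, ...) {
  cat("Time-response model:", x$species_name,
      if (!is.na(x$taxon_class)) paste0("(", x$taxon_class, ")"), "\n")
  cat(sprintf("  ln(EC) = %.4g %+.4g * ln(day)\n", x$intercept, x$slope))
  cat(sprintf("  D^2 = %.4g  LOOCV-MSE = %.4g  n = %s  inflection day = %s\n",
              x$dsquared, x$loocv_mse, x$n_points, x$inflection_day))
  if (length(x$removed_points)) {
    cat("  influential points removed:",
        paste(x$removed_points, collapse = ", "), "\n")
  }
  invisible(x)
}

#' t-based confidence intervals for the regression coefficients
#'
#' @param model a fitted `time_response_model` (needs standard errors
#'   and residual degrees of freedom).
#' @param level confidence level (default 0.95).
#' @return a 2x2 matrix (rows intercept, slope; columns lower, upper).
#' @export
coef_ci <- function(model, level = 0.95) {
  stopifnot(inherits(model, "time_response_model"))
  if (is.na(model$df_residual) || is.na(model$se_slope)) {
    stop("model lacks standard errors / degrees of freedom", call. = FALSE)
  }
  tq <- qt(1 - (1 - level) / 2, model$df_residual)
  est <- c(model$intercept, model$slope)
  se <- c(model$se_intercept, model$se_slope)
  out <- cbind(lower = est - tq * se, upper = est + tq * se)
  rownames(out) <- c("intercept", "slope")
  out
}

#' Predict effect concentrations by day, with bootstrap intervals
#'
#' Point prediction is `exp(intercept + slope * ln(day))`.  Confidence
#' intervals come from a parametric bootstrap: coefficient pairs are
#' drawn from the estimated sampling distribution of (intercept, slope)
#' (bivariate normal with the fitted covariance), each replicate's
#' prediction is exponentiated, and the 2.5/97.5 percentiles are
#' reported.  Set `method = "residual"` to resample residuals onto the
#' fitted log-line and refit instead (requires the original series).
#'
#' Predictions beyond the model's inflection day, or beyond
#' `extrapolation_limit` days, carry a warning flag in the `warning`
#' column: the fitted power law is unvalidated there.
#'
#' @param model a `time_response_model`.
#' @param days positive integer day(s), >= 1.
#' @param n_boot bootstrap replicates (default 1000; 0 skips intervals).
#' @param seed integer seed for the bootstrap.
#' @param level interval level (default 0.95).
#' @param method `"coef"` (default; coefficient-sampling) or
#'   `"residual"`.
#' @param series original bioassay series, only for
#'   `method = "residual"`.
#' @param extrapolation_limit day beyond which predictions are flagged
#'   (default 100).
#' @return data frame with columns `day`, `point`, `ci_lower`,
#'   `ci_upper`, `warning` (logical extrapolation flag).
#' @examples
#' m <- time_response_model(intercept = log(100), slope = -1)
#' predict_ec(m, c(1, 10), n_boot = 0)
#' @export
predict_ec <- function(model, days, n_boot = 1000, seed = 1, level = 0.95,
                       method = c("coef", "residual"), series = NULL,
                       extrapolation_limit = 100) {
  stopifnot(inherits(model, "time_response_model"))
  method <- match.arg(method)
  if (any(days < 1)) stop("days must be >= 1", call. = FALSE)
  point <- exp(model$intercept + model$slope * log(days))
  flag_day <- min(model$inflection_day, extrapolation_limit, na.rm = TRUE)
  out <- data.frame(day = days, point = point,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    warning = days > flag_day)
  if (n_boot > 0) {
    draws <- .draw_coefs(model, n_boot, seed, method, series)
    pred <- exp(draws[, 1, drop = FALSE] %*% t(rep(1, length(days))) +
                  draws[, 2, drop = FALSE] %*% t(log(days)))
    qs <- apply(pred, 2, quantile, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                names = FALSE)
    out$ci_lower <- pmin(qs[1, ], point)
    out$ci_upper <- pmax(qs[2, ], point)
  }
  out
}

.draw_coefs <- function(model, n_boot, seed, method, series) {
  set.seed(as.integer(seed))
  if (method == "coef") {
    if (is.null(model$vcov)) {
      stop("model has no coefficient covariance; refit with fit_time_response()",
           call. = FALSE)
    }
    MASS::mvrnorm(n_boot, mu = c(model$intercept, model$slope),
                  Sigma = model$vcov)
  } else {
    if (is.null(series)) {
      stop("method = 'residual' needs the original bioassay series", call. = FALSE)
    }
    ld <- log(series$duration)
    fitted_log <- model$intercept + model$slope * ld
    res <- log(series$effect_concentration) - fitted_log
    t(vapply(seq_len(n_boot), function(b) {
      y_star <- fitted_log + sample(res, length(res), replace = TRUE)
      coef(lm(y_star ~ ld))
    }, numeric(2)))
  }
}

#' Locate the inflection day of a time-response model
#'
#' The day beyond which successive modelled daily toxicity estimates
#' stop changing appreciably, used to bound the usable exposure window.
#' Under the `relative_change` rule this is the first whole day `d`
#' (up to `horizon`) at which the relative decline from day `d` to day
#' `d + 1`, `1 - ((d + 1) / d) ^ slope`, falls below `threshold`.
#'
#' @param model a `time_response_model` with negative slope (a bare
#'   numeric slope is also accepted).
#' @param rule inflection rule; only `"relative_change"` is currently
#'   implemented (the argument exists so alternative rules can plug
#'   in).
#' @param threshold relative daily change below which toxicity is
#'   considered stable (default 0.05, i.e. 5% per day).
#' @param horizon last day scanned (default 365); returned with a
#'   warning if the threshold is never met.
#' @return a positive integer day.
#' @examples
#' inflection_day(time_response_model(5, -1.827)) # 37
#' @export
inflection_day <- function(model, rule = "relative_change", threshold = 0.05,
                           horizon = 365) {
  rule <- match.arg(rule, "relative_change")
  slope <- if (inherits(model, "time_response_model")) model$slope else as.numeric(model)
  if (!is.finite(slope) || slope >= 0) {
    stop("inflection day is undefined for a non-negative slope", call. = FALSE)
  }
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  d <- seq_len(horizon)
  rel <- 1 - ((d + 1) / d)^slope
  hit <- which(rel < threshold)
  if (!length(hit)) {
    warning("relative change never fell below ", threshold, " within ",
            horizon, " days; returning the horizon", call. = FALSE)
    return(as.integer(horizon))
  }
  as.integer(hit[1])
}

#' Export a model report as JSON
#'
#' Mirrors the conventional regression-table layout: coefficient,
#' standard error, t value, two-sided probability, plus diagnostics and
#' the inflection day.
#'
#' @param model a `time_response_model`.
#' @return one-element character vector of JSON.
#' @export
time_response_report <- function(model) {
  stopifnot(inherits(model, "time_response_model"))
  tval <- c(model$intercept / model$se_intercept, model$slope / model$se_slope)
  pval <- if (!is.na(model$df_residual)) {
    2 * stats::pt(-abs(tval), model$df_residual)
  } else rep(NA_real_, 2)
  rec <- list(
    species = model$species_name,
    taxon_class = model$taxon_class,
    coefficients = list(
      y_intercept = list(estimate = model$intercept, se = model$se_intercept,
                         t_value = tval[1], probability = pval[1]),
      ln_exposure_duration = list(estimate = model$slope, se = model$se_slope,
                                  t_value = tval[2], probability = pval[2])),
    dsquared = model$dsquared,
    loocv_mse = model$loocv_mse,
    n_points = model$n_points,
    removed_points = model$removed_points,
    inflection_day = model$inflection_day)
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
}

#' Read a reference time-series bioassay table
#'
#' Expected columns: `species`, `class`, `duration_days`, `endpoint`,
#' `effect_concentration_ugL`, `source_id`.
#'
#' @param path CSV path.
#' @return a data frame with one row per duration-EC pair, columns
#'   `species`, `class`, `duration`, `effect_concentration`,
#'   `endpoint`, `source_id`.
#' @export
read_reference_series <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "class", "duration_days", "effect_concentration_ugL")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("reference series is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  data.frame(
    species = raw$species,
    class = raw$class,
    duration = as.numeric(raw$duration_days),
    effect_concentration = as.numeric(raw$effect_concentration_ugL),
    endpoint = if ("endpoint" %in% names(raw)) raw$endpoint else "LC50",
    source_id = if ("source_id" %in% names(raw)) raw$source_id else "",
    stringsAsFactors = FALSE)
}
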