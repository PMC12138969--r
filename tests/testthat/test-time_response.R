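test_that("an exact power law is fitted exactly", {
  t <- c(1, 2, 4, 8, 16)
  s <- data.frame(duration = t, effect_concentration = 100 / t)
  m <- fit_time_response(s)
  expect_equal(m$slope, -1, tolerance = 1e-12)
  expect_equal(m$intercept, log(100), tolerance = 1e-12)
  expect_equal(m$dsquared, 1, tolerance = 1e-12)
  expect_equal(m$loocv_mse, 0, tolerance = 1e-20)
  expect_equal(m$fit_window_max_day, 16)
})

test_that("the GLM fit equals the normal-equations solution", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    d <- sort(stats::runif(n, 0.5, 30))
    ec <- exp(stats::rnorm(1, 5, 2) + stats::rnorm(1, -2, 1) * log(d) +
                stats::rnorm(n, 0, 0.3))
    s <- data.frame(duration = d, effect_concentration = ec)
    m <- fit_time_response(s, cooks_threshold = Inf)
    o <- ls_oracle(d, ec)
    expect_equal(m$intercept, unname(o["intercept"]), tolerance = 1e-10)
    expect_equal(m$slope, unname(o["slope"]), tolerance = 1e-10)
    # explained deviance equals squared correlation for the Gaussian identity fit
    fitted_log <- m$intercept + m$slope * log(d)
    expect_equal(m$dsquared, stats::cor(log(ec), fitted_log)^2, tolerance = 1e-9)
  }
})

test_that("two-point geometry pins the slope", {
  s <- data.frame(duration = c(1, 1, 10, 10, 10),
                  effect_concentration = c(100, 100, 10, 10, 10))
  m <- fit_time_response(s)
  expect_equal(m$slope, (log(10) - log(100)) / (log(10) - log(1)),
               tolerance = 1e-12)
})

test_that("undersized or degenerate series are rejected", {
  s <- data.frame(duration = c(1, 2, 4), effect_concentration = c(3, 2, 1))
  expect_error(fit_time_response(s), "at least 5")
  s2 <- data.frame(duration = rep(2, 6), effect_concentration = 6:1)
  expect_error(fit_time_response(s2), "durations are equal")
  s3 <- data.frame(duration = 1:5, effect_concentration = c(-1, 1, 1, 1, 1))
  expect_error(fit_time_response(s3), "positive")
})

test_that("influential points are removed in one logged pass", {
  t <- c(1, 2, 4, 8, 16, 32)
  ec <- 100 * t^-1.5
  ec[6] <- ec[6] * 1e4  # gross outlier at high leverage
  s <- data.frame(duration = t, effect_concentration = ec)
  m <- fit_time_response(s)
  expect_equal(m$removed_points, 6L)
  expect_equal(m$n_points, 5)
  expect_equal(m$slope, -1.5, tolerance = 1e-10)
  # with the rule disabled the outlier stays in (and drags the slope up,
  # here past zero, which warns)
  m2 <- suppressWarnings(fit_time_response(s, cooks_threshold = Inf))
  expect_length(m2$removed_points, 0)
  expect_gt(m2$slope, m$slope)
})

test_that("non-negative slopes warn rather than error", {
  s <- data.frame(duration = c(1, 2, 4, 8, 16),
                  effect_concentration = c(10, 11, 10.5, 12, 11.5))
  expect_warning(m <- fit_time_response(s), "non-negative")
  expect_true(is.na(m$inflection_day))
})

test_that("published-style coefficients reproduce hand-evaluated predictions", {
  daphnia <- time_response_model(18.92, -3.892, species_name = "Daphnia magna")
  p10 <- predict_ec(daphnia, 10, n_boot = 0)
  expect_equal(p10$point, exp(18.92 - 3.892 * log(10)), tolerance = 1e-12)
  expect_equal(p10$point, 2.12e4, tolerance = 0.01)

  mayfly <- time_response_model(4.646, -1.827, species_name = "Deleatidium sp.")
  p2 <- predict_ec(mayfly, 2, n_boot = 0)
  expect_equal(p2$point, exp(4.646 - 1.827 * log(2)), tolerance = 1e-12)
  expect_equal(p2$point, 29.4, tolerance = 0.01)

  # day 1 is the exponentiated intercept
  expect_equal(predict_ec(daphnia, 1, n_boot = 0)$point, exp(18.92))
})

test_that("predictions decline with day and intervals behave", {
  t <- c(1, 2, 4, 7, 14, 28)
  s <- data.frame(duration = t,
                  effect_concentration = exp(5 - 1.8 * log(t) +
                                               c(0.1, -0.05, 0.08, -0.1, 0.03, -0.06)))
  m <- fit_time_response(s)
  pr <- predict_ec(m, 1:50, n_boot = 400, seed = 8)
  expect_true(all(diff(pr$point) < 0))
  expect_true(all(pr$ci_lower <= pr$point & pr$point <= pr$ci_upper))
  expect_identical(pr, predict_ec(m, 1:50, n_boot = 400, seed = 8))
  # extrapolation flag beyond the inflection day / guard
  flag_from <- min(m$inflection_day, 100)
  expect_equal(pr$warning, pr$day > flag_from)
  expect_error(predict_ec(m, 0), ">= 1")
  # residual resampling variant also brackets the point estimate
  pr2 <- predict_ec(m, c(2, 10), n_boot = 200, seed = 3,
                    method = "residual", series = s)
  expect_true(all(pr2$ci_lower <= pr2$point & pr2$point <= pr2$ci_upper))
})

test_that("inflection day matches a brute-force scan of the relative-change rule", {
  for (slope in c(-0.737, -1.827, -3.892, -0.2, -6)) {
    for (thr in c(0.05, 0.1, 0.01)) {
      m <- suppressWarnings(time_response_model(5, slope,
                                                inflection_threshold = thr))
      expect_equal(suppressWarnings(inflection_day(m, threshold = thr)),
                   inflection_oracle(slope, thr))
    }
  }
  expect_equal(inflection_day(time_response_model(5, -1.827), threshold = 1), 1)
  expect_error(inflection_day(time_response_model(5, 0.5)), "non-negative")
  steep <- suppressWarnings(time_response_model(5, -50))
  expect_warning(d <- inflection_day(steep, threshold = 1e-4, horizon = 50),
                 "horizon")
  expect_equal(d, 50L)
})

test_that("model reports carry the regression-table fields", {
  t <- c(2, 4, 7, 14, 28)
  s <- data.frame(duration = t,
                  effect_concentration = exp(4.6 - 1.8 * log(t) +
                                               c(0.05, -0.1, 0.02, 0.08, -0.04)))
  m <- fit_time_response(s, species_name = "ref sp", taxon_class = "Insecta")
  rec <- jsonlite::fromJSON(time_response_report(m))
  expect_equal(rec$species, "ref sp")
  expect_equal(rec$coefficients$ln_exposure_duration$estimate, m$slope)
  expect_lt(rec$coefficients$ln_exposure_duration$probability, 0.01)
  expect_equal(rec$inflection_day, m$inflection_day)
})
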