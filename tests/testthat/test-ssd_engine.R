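test_that("log-normal MLE matches its closed form", {
  f <- fit_ssd(exp(1:3), "log_normal", min_n = 3)
  expect_equal(unname(f$params["meanlog"]), 2)
  expect_equal(unname(f$params["sdlog"]), sqrt(2 / 3))

  set.seed(101)
  for (i in 1:10) {
    x <- rlnorm(sample(8:64, 1), stats::rnorm(1, 0, 3), exp(stats::rnorm(1)))
    f <- fit_ssd(x, "log_normal")
    lx <- log(x)
    expect_equal(unname(f$params["meanlog"]), mean(lx), tolerance = 1e-10)
    expect_equal(unname(f$params["sdlog"]),
                 sqrt(mean((lx - mean(lx))^2)), tolerance = 1e-10)
  }
})

test_that("large-sample fits recover generating parameters", {
  set.seed(7)
  x <- rlnorm(10000, 0, 1)
  f <- fit_ssd(x, "log_normal")
  expect_lt(abs(f$params[["meanlog"]]), 0.05)
  expect_lt(abs(f$params[["sdlog"]] - 1), 0.05)

  g <- rlgumbel(10000, location = 1, scale = 0.5)
  fg <- fit_ssd(g, "log_gumbel")
  expect_lt(abs(fg$params[["location"]] - 1), 0.05)
  expect_lt(abs(fg$params[["scale"]] - 0.5), 0.05)

  ll <- rllogis(10000, location = -2, scale = 0.7)
  fl <- fit_ssd(ll, "log_logistic")
  expect_lt(abs(fl$params[["location"]] + 2), 0.05)
  expect_lt(abs(fl$params[["scale"]] - 0.7), 0.05)

  gm <- rgamma(10000, shape = 2, rate = 0.5)
  fgm <- fit_ssd(gm, "gamma")
  expect_lt(abs(fgm$params[["shape"]] - 2), 0.1)
})

test_that("degenerate and undersized samples are rejected", {
  expect_error(fit_ssd(rep(1, 8), "log_normal"), "degenerate")
  expect_error(fit_ssd(rlnorm(5), "log_normal"), "at least 8")
  expect_error(fit_ssd(c(-1, rlnorm(10)), "log_normal"), "positive")
})

test_that("selection takes minimum AICc with fixed-order tie-breaking", {
  set.seed(21)
  x <- rlnorm(32, 1, 1)
  fits <- fit_ssd_all(x)
  sel <- select_ssd(fits)
  aiccs <- vapply(fits, function(f) f$aicc, numeric(1))
  expect_equal(sel$aicc, min(aiccs))
  expect_named(attr(sel, "rationale"))

  one <- fits[1]
  expect_equal(select_ssd(one)$family, names(one))

  # construct an exact tie: family order must break it
  fa <- fits[["weibull"]]
  fb <- fits[["log_normal"]]
  fb$aicc <- fa$aicc
  expect_equal(select_ssd(list(fa, fb))$family, "log_normal")
  expect_error(select_ssd(list()), "no fits")
})

test_that("protective concentrations are the matching lower quantiles", {
  f <- structure(list(family = "log_normal",
                      params = c(meanlog = 2, sdlog = 0.8)),
                 class = "ssd_fit")
  expect_equal(protective_concentration(f, 50), exp(2))
  f2 <- structure(list(family = "log_normal",
                       params = c(meanlog = log(100), sdlog = log(10))),
                  class = "ssd_fit")
  expect_equal(protective_concentration(f2, 95),
               exp(log(100) + qnorm(0.05) * log(10)), tolerance = 1e-12)
  expect_lt(protective_concentration(f, 99), protective_concentration(f, 80))
  expect_error(protective_concentration(f, 100), "between 0 and 100")
  expect_error(protective_concentration(f, 0), "between 0 and 100")
})

test_that("PAF inverts PC for every family over fuzzed parameters", {
  set.seed(33)
  for (rep in 1:5) {
    x <- rlnorm(32, stats::rnorm(1, 2, 1), stats::runif(1, 0.4, 2))
    for (fam in ssd_families()) {
      f <- fit_ssd(x, fam)
      for (p in c(99, 95, 90, 80, 50, 20)) {
        expect_lt(abs(fraction_affected(f, protective_concentration(f, p)) -
                        (100 - p)), 1e-9)
      }
      expect_equal(fraction_affected(f, protective_concentration(f, 50)), 50,
                   tolerance = 1e-9)
      # CDF sanity at extreme quantiles
      expect_lt(fraction_affected(f, protective_concentration(f, 99.999)), 0.01)
      expect_gt(fraction_affected(f, protective_concentration(f, 0.001)), 99.9)
      pcs <- protective_concentration(f, c(99, 95, 90, 80))
      expect_true(all(diff(pcs) > 0))
    }
  }
})

test_that("rescaling concentrations rescales every PC proportionally", {
  set.seed(55)
  x <- rlnorm(32, 2, 1.3)
  for (fam in ssd_families()) {
    f1 <- fit_ssd(x, fam)
    for (k in c(1000, 1 / 997)) {
      f2 <- fit_ssd(k * x, fam)
      expect_equal(protective_concentration(f2, c(99, 95, 90, 80)),
                   k * protective_concentration(f1, c(99, 95, 90, 80)),
                   tolerance = 1e-9)
    }
  }
})

test_that("bootstrap CIs are seeded, ordered and validated", {
  set.seed(3)
  x <- rlnorm(32, 1, 1)
  b1 <- bootstrap_ci(x, "log_normal", n_boot = 300, seed = 42)
  b2 <- bootstrap_ci(x, "log_normal", n_boot = 300, seed = 42)
  expect_identical(b1, b2)
  expect_true(all(b1$ci_lower <= b1$point & b1$point <= b1$ci_upper))
  f <- fit_ssd(x, "log_normal")
  expect_equal(b1$point, protective_concentration(f, b1$protection_pct))
  expect_error(bootstrap_ci(x, "log_normal", n_boot = 0), "n_boot")
  bm <- bootstrap_ci(x, "log_normal", n_boot = 100, seed = 1,
                     pc_point = "bootstrap_median")
  expect_true(all(bm$ci_lower <= bm$point & bm$point <= bm$ci_upper))
})

test_that("fit reports serialize with a stable key order", {
  set.seed(4)
  f <- fit_ssd(rlnorm(32, 1, 1), "weibull")
  js <- ssd_fit_report(f, seed = 9, n_boot = 100)
  rec <- jsonlite::fromJSON(js)
  expect_identical(names(rec),
                   c("family", "params", "n", "loglik", "aicc", "gof",
                     "seed", "n_boot"))
  expect_equal(rec$n, 32)
  expect_equal(rec$family, "weibull")
})

test_that("log-Gumbel and log-logistic primitives are coherent", {
  p <- c(0.01, 0.2, 0.5, 0.9, 0.999)
  expect_equal(plgumbel(qlgumbel(p, 1.3, 0.6), 1.3, 0.6), p, tolerance = 1e-12)
  expect_equal(pllogis(qllogis(p, -0.5, 1.1), -0.5, 1.1), p, tolerance = 1e-12)
  # density integrates to the CDF increment
  q <- qlgumbel(c(0.1, 0.9), 0, 1)
  expect_equal(stats::integrate(dlgumbel, q[1], q[2], location = 0,
                                scale = 1)$value,
               0.8, tolerance = 1e-6)
  expect_equal(qllogis(0.5, log(100), 1), 100)  # location is the log-median
})
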