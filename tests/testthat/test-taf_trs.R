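test_that("TAF tables self-calibrate and follow the power law", {
  m <- time_response_model(log(100), -1)
  taf <- compute_taf_table(m, ec_measured = 100, measured_day = 1)
  expect_equal(unname(taf$factors["1"]), 1)
  expect_equal(unname(taf$factors["10"]), 0.1)
  expect_true(all(diff(taf$factors) < 0))

  m2 <- time_response_model(4.2, -1.7)
  d0 <- 4
  taf2 <- compute_taf_table(m2, ec_measured = exp(4.2 - 1.7 * log(d0)),
                            measured_day = d0)
  expect_equal(unname(taf2$factors[as.character(d0)]), 1, tolerance = 1e-12)
  # doubling the day multiplies the factor by 2^slope, for every day
  f <- taf2$factors
  for (d in 1:50) {
    expect_equal(unname(f[as.character(2 * d)] / f[as.character(d)]),
                 2^m2$slope, tolerance = 1e-12)
  }
  expect_error(compute_taf_table(NULL, 1, 1), "time_response_model")
  expect_error(compute_taf_table(m, -1, 1), "positive")
})

test_that("class-wise adjustment multiplies by the day's factor", {
  ss <- structure(data.frame(
    species_name = c("A", "B", "C"),
    value = c(100, 10, 1),
    taxon_class = c("Insecta", "Insecta", "Malacostraca"),
    medium = "freshwater", n_source_records = 1L,
    value_kind = "acute_estimated", stringsAsFactors = FALSE),
    class = c("sensitivity_set", "data.frame"))
  tafs <- list(
    Insecta = compute_taf_table(time_response_model(log(100), -1), 100, 1),
    Malacostraca = compute_taf_table(time_response_model(log(50), -0.5), 50, 1))
  cmap <- c(Insecta = "Insecta", Malacostraca = "Malacostraca")

  day1 <- adjust_toxicity(ss, tafs, cmap, 1)   # TAF(1) = 1 everywhere
  expect_equal(day1$value, ss$value)
  day10 <- adjust_toxicity(ss, tafs, cmap, 10)
  expect_equal(day10$value[1:2], c(10, 1))      # x 0.1
  expect_equal(day10$value[3], 10^-0.5)         # x 10^-0.5

  # unmapped class errors and names the species; exclude drops silently
  ss$taxon_class[3] <- "Ostracoda"
  expect_error(adjust_toxicity(ss, tafs, cmap, 1), "Ostracoda.*C")
  dropped <- adjust_toxicity(ss, tafs, c(cmap, Ostracoda = "exclude"), 1)
  expect_equal(dropped$species_name, c("A", "B"))
})

test_that("a zero-slope surface is time-invariant", {
  b <- single_class_bundle(seed = 5)
  ss <- aggregate_species(b$community$records)
  flat <- list(Insecta = suppressWarnings(
    time_response_model(log(20), 0, species_name = "flat")))
  # slope 0: prediction constant; calibrating at the prediction makes TAF = 1
  cfg <- trs_config(c(Insecta = "Insecta"),
                    list(Insecta = list(ec_measured = 20, measured_day = 2)),
                    days = 1:100, forced_family = "log_normal")
  surf <- build_trs(ss, flat, cfg)
  pcs <- matrix(surf$pc_table$point, nrow = 4)
  expect_true(all(apply(pcs, 1, function(r) max(abs(r - r[1]))) < 1e-12))
})

test_that("the day-1 slice equals the unadjusted acute SSD when TAF(1) = 1", {
  b <- single_class_bundle(seed = 6)
  ss <- aggregate_species(b$community$records)
  m <- fit_time_response(b$reference_series$Insecta)
  cal <- list(Insecta = list(ec_measured = exp(m$intercept), measured_day = 1))
  cfg <- trs_config(c(Insecta = "Insecta"), cal, days = 1:3,
                    forced_family = "log_normal")
  surf <- build_trs(ss, list(Insecta = m), cfg)
  direct <- fit_ssd(ss$value, "log_normal")
  expect_equal(query_surface(surf, 1, "pc", 95),
               protective_concentration(direct, 95), tolerance = 1e-10)
})

test_that("surface queries, crossings and exports are consistent", {
  b <- single_class_bundle(seed = 12)
  ss <- aggregate_species(b$community$records)
  m <- fit_time_response(b$reference_series$Insecta)
  cfg <- trs_config(b$class_map, b$calibration, days = 1:60,
                    forced_family = "log_normal", seed = 2)
  surf <- build_trs(ss, list(Insecta = m), cfg)

  # pc -> paf round trip at an arbitrary day
  pc95 <- query_surface(surf, 30, "pc", 95)
  expect_equal(query_surface(surf, 30, "paf", pc95), 5, tolerance = 1e-9)
  expect_error(query_surface(surf, 101, "pc", 95), "outside the surface")

  # first_day_below: immediate crossing at a generous threshold
  day1_pc95 <- query_surface(surf, 1, "pc", 95)
  expect_equal(first_day_below(surf, 95, day1_pc95 * 2), 1L)
  expect_true(is.na(first_day_below(surf, 95, 1e-30)))
  thr <- sqrt(query_surface(surf, 20, "pc", 95) *
                query_surface(surf, 21, "pc", 95))  # between days 20 and 21
  fd <- first_day_below(surf, 95, thr)
  expect_equal(query_surface(surf, fd, "pc", 95) < thr, TRUE)
  expect_gt(query_surface(surf, fd - 1, "pc", 95), thr)

  # export: one row per day, exact round trip, 2-significant-figure display
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_trs_table(surf, tmp)
  tab <- read.csv(tmp)
  expect_equal(nrow(tab), 60)
  expect_identical(tab$pc95, surf$pc_table$point[surf$pc_table$protection_pct == 95])
  expect_identical(tab$pc95_2sf, signif(tab$pc95, 2))
})

test_that("PC levels are ordered and decline with day under a fixed family", {
  b <- single_class_bundle(seed = 13, beta = -1.1)
  ss <- aggregate_species(b$community$records)
  m <- fit_time_response(b$reference_series$Insecta)
  for (fam in c("log_normal", "log_gumbel", "weibull")) {
    cfg <- trs_config(b$class_map, b$calibration, days = 1:40,
                      forced_family = fam)
    surf <- build_trs(ss, list(Insecta = m), cfg)
    wide <- matrix(surf$pc_table$point, nrow = 4)  # rows: 99, 95, 90, 80
    expect_true(all(wide[1, ] <= wide[2, ] & wide[2, ] <= wide[3, ] &
                      wide[3, ] <= wide[4, ]))
    expect_true(all(diff(t(wide)) < 0))
  }
})

test_that("rebuilding with the same seed reproduces the surface bitwise", {
  b <- single_class_bundle(seed = 14)
  ss <- aggregate_species(b$community$records)
  m <- fit_time_response(b$reference_series$Insecta)
  cfg <- trs_config(b$class_map, b$calibration, days = 1:10,
                    forced_family = "log_normal", n_boot = 50, seed = 77)
  s1 <- build_trs(ss, list(Insecta = m), cfg)
  s2 <- build_trs(ss, list(Insecta = m), cfg)
  expect_identical(s1$pc_table, s2$pc_table)
  t1 <- withr::local_tempfile(fileext = ".csv")
  t2 <- withr::local_tempfile(fileext = ".csv")
  export_trs_table(s1, t1)
  export_trs_table(s2, t2)
  expect_identical(readLines(t1), readLines(t2))
  expect_true(all(s1$pc_table$ci_lower <= s1$pc_table$point))
})
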