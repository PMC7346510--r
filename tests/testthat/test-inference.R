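test_that("Mann-Whitney W matches the brute-force pair count", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$W, 0)
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$W, 9)
  set.seed(3)
  for (i in 1:30) {
    a <- sample(1:20, sample(2:8, 1), replace = TRUE)
    b <- sample(1:20, sample(2:8, 1), replace = TRUE)
    expect_equal(unname(mann_whitney(a, b)$W), brute_mw_U(a, b))
  }
})

test_that("Fisher exact p matches brute-force enumeration", {
  # the study's first-night departure contrast: 6/14 vs 7/21
  tab <- rbind(c(6, 8), c(7, 14))
  expect_equal(fisher_exact_2x2(tab), 0.72, tolerance = 0.01)
  expect_equal(fisher_exact_2x2(tab), brute_fisher_p(tab), tolerance = 1e-9)
  set.seed(4)
  for (i in 1:30) {
    t2 <- matrix(sample(0:8, 4, replace = TRUE), 2)
    expect_equal(fisher_exact_2x2(t2), brute_fisher_p(t2), tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(1, -1, 2, 3), 2)), "non-negative")
})

test_that("linear fits report exact fits and honest transforms", {
  d <- data.frame(x = 1:10, y = 3 + 2 * (1:10))
  f <- suppressWarnings(fit_linear_model(y ~ x, d)) # summary warns on exact fits
  expect_equal(f$r_squared, 1)
  expect_equal(unname(f$coefficients[, 1]), c(3, 2))
  d2 <- data.frame(x = 1:10, y = 10^(1 + 0.1 * (1:10)))
  f2 <- suppressWarnings(fit_linear_model(y ~ x, d2, log10_response = TRUE))
  expect_equal(unname(f2$coefficients[, 1]), c(1, 0.1))
  expect_error(fit_linear_model(y ~ x, data.frame(x = 1:3, y = c(-1, 1, 2)),
                                log10_response = TRUE), "positive")
})

test_that("the F test is calibrated on null data", {
  set.seed(71)
  rej <- 0L
  for (r in 1:1000) {
    d <- data.frame(x = rnorm(20), y = rnorm(20))
    if (fit_linear_model(y ~ x, d)$p_overall < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 1000, 0.03)
  expect_lt(rej / 1000, 0.07)
})

test_that("weather is matched to the sunset hour with a tolerance window", {
  # hourly rows around the Helgoland capture-day sunsets, carrying the
  # conditions reported for the two capture days
  w <- data.frame(
    ts = c("2018-09-02T18:00:00", "2018-09-02T19:00:00",
           "2018-10-06T17:00:00"),
    wind_speed = c(7.5, 9.9, 6.6), wind_dir = c(70, 120, 350),
    precip = c(0, 0, 0), temp = c(19, 18, 14))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(w, f, row.names = FALSE, quote = FALSE)
  weather <- read_weather(f)
  out <- attach_weather(as.Date(c("2018-09-02", "2018-10-06", "2018-11-20")),
                        weather, 54.1833, 7.8833)
  # sunset 18:17 UTC rounds to the 18:00 row; 16:53 rounds to 17:00
  expect_equal(out$wind_dir[1:2], c(70, 350))
  expect_equal(out$wind_speed[1:2], c(7.5, 6.6))
  expect_equal(out$temp[1:2], c(19, 14))
  expect_equal(out$wind_toward[1:2], c(250, 170))
  expect_true(out$missing[3]) # no November rows within +/- 3 h
  unlink(f)
})

test_that("the bird table reader tolerates the historical misspelling", {
  b <- data.frame(Species = c("CR", "CR", "ER", "ER"), Muscle = 2,
                  Wing = c(80, 81, 72, 73), Bodymass = c(14, 14.5, 15, 15.5),
                  days.on.island = c(1, 2, 1, 3),
                  dep.realtive.night = c(0.2, 0.3, 0.4, 0.5))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(b, f, row.names = FALSE)
  rb <- read_bird_table(f)
  expect_true("dep.relative.night" %in% names(rb))
  expect_false("dep.realtive.night" %in% names(rb))
  unlink(f)
})

test_that("store-dependent models use only first-night departers", {
  sim <- simulate_cohort(sim_config(seed = 14))
  rep <- run_study(sim$birds, circ_reps = 200, seed = 2)
  n_first <- sum(sim$birds$days.on.island == 1)
  expect_equal(rep$tests$beta_first_night$n, n_first)
  expect_equal(rep$tests$lm_timing_first_night$n, n_first)
  # all-bird models keep everyone with an ascertained departure
  expect_equal(rep$tests$beta_all$n, nrow(sim$birds))
})

test_that("beta-regression coefficients are recovered from a large cohort", {
  cfg <- sim_config(seed = 15, n_birds = c(CR = 250L, ER = 250L))
  # make every bird a first-night departer so the timing model sees all 500
  cfg$species$CR$dep_intercept <- 20
  cfg$species$ER$dep_intercept <- 20
  sim <- simulate_cohort(cfg)
  rep <- run_study(sim$birds, circ_reps = 100, seed = 3)
  fit <- rep$tests$beta_first_night
  truth <- c(-1.20, 1.15, -0.45)
  expect_true(all(abs(coef(fit) - truth) <= 2 * fit$se))
})

test_that("a table of unascertained departures yields an empty report", {
  sim <- simulate_cohort(sim_config(seed = 16))
  b <- sim$birds
  b$days.on.island <- NA
  rep <- run_study(b)
  expect_length(rep$tests, 0)
  expect_match(rep$skipped, "no birds")
})

test_that("the report prints and serialises to JSON", {
  sim <- simulate_cohort(sim_config(seed = 17))
  rep <- run_study(sim$birds, circ_reps = 100, seed = 4)
  expect_output(print(rep), "Rayleigh")
  expect_output(print(rep), "Beta regression")
  js <- jsonlite::fromJSON(report_json(rep))
  expect_equal(js$n$CR, 14)
  expect_true(is.numeric(js$tests$beta_first_night$coefficients$stores_scaled))
  f <- tempfile(fileext = ".json")
  report_json(rep, f)
  expect_true(file.exists(f))
  unlink(f)
})
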