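test_that("the same seed reproduces the cohort and stream bit for bit", {
  a <- simulate_cohort(sim_config(seed = 11))
  b <- simulate_cohort(sim_config(seed = 11))
  expect_identical(a, b)
  sa <- simulate_detections(a$truth[1:3, ], sim_config(seed = 11))
  sb <- simulate_detections(b$truth[1:3, ], sim_config(seed = 11))
  expect_identical(sa, sb)
})

test_that("adding birds does not perturb earlier per-bird draws", {
  small <- simulate_cohort(sim_config(seed = 4, n_birds = c(CR = 5L, ER = 0L)))
  large <- simulate_cohort(sim_config(seed = 4, n_birds = c(CR = 9L, ER = 0L)))
  # raw per-bird draws are keyed by bird index, so the first five agree
  expect_equal(large$birds$Wing[1:5], small$birds$Wing)
  expect_equal(large$truth$energy_stores[1:5], small$truth$energy_stores)
  expect_equal(large$truth$bearing[1:5], small$truth$bearing)
})

test_that("a degenerate energy-store range yields body mass = lean mass", {
  cfg <- sim_config(seed = 8, stores_range = c(0, 0))
  sim <- simulate_cohort(cfg)
  lean <- lean_body_mass(sim$birds$Species, sim$birds$Muscle, sim$birds$Wing)
  expect_equal(sim$birds$Bodymass, lean)
})

test_that("a flat departure model at logit(0.5) gives a fair coin", {
  cfg <- sim_config(seed = 21, n_birds = c(CR = 10000L, ER = 0L))
  cfg$species$CR$dep_intercept <- qlogis(0.5)
  cfg$species$CR$dep_slope <- 0
  sim <- simulate_cohort(cfg)
  frac <- mean(sim$truth$departed_first_night)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000)) # within 3 binomial SE
})

test_that("a steeper store effect raises departures of fat birds", {
  base <- sim_config(seed = 22, n_birds = c(CR = 10000L, ER = 0L))
  base$species$CR$dep_slope <- 0
  steep <- sim_config(seed = 22, n_birds = c(CR = 10000L, ER = 0L))
  steep$species$CR$dep_slope <- 2
  f0 <- with(simulate_cohort(base)$truth,
             mean(departed_first_night[stores_scaled > 0]))
  f2 <- with(simulate_cohort(steep)$truth,
             mean(departed_first_night[stores_scaled > 0]))
  expect_gt(f2, f0)
})

test_that("a study-sized cohort spans the observed store interval", {
  sim <- simulate_cohort(sim_config(seed = 1))
  for (sp in c("CR", "ER")) {
    e <- sim$truth$energy_stores[sim$truth$species == sp]
    expect_true(all(e >= -0.05 & e <= 0.2))
    expect_gt(diff(range(e)), 0.15) # draws fill most of [-0.05, 0.2]
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(stores_range = c(-1.5, 0)), "exceed -1")
  bad <- sim_config()
  expect_error({
    cfg <- sim_config(species = modifyList(sim_config()$species,
      list(CR = modifyList(sim_config()$species$CR,
                           list(muscle_probs = c(`3` = 1))))))
  }, "without a lean-mass equation") # no CR/3 calibration exists
  expect_error(sim_config(signal = modifyList(sim_config()$signal,
                                              list(sampling_interval_s = 0))),
               "sampling interval")
})

test_that("a stationary bird gives constant noiseless signals and no event", {
  cfg <- sim_config(seed = 9, n_birds = c(CR = 1L, ER = 0L))
  cfg$signal$noise_sd_dB <- 0
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  tr$take_off_time <- as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC")
  stream <- simulate_detections(tr, cfg)
  per_ant <- tapply(stream$signal, stream$antenna_id, function(s) length(unique(s)))
  expect_true(all(per_ant == 1))
  expect_identical(segment_departure_event(stream)$qc, "no_event_found")
})

test_that("a noiseless departure at 90 degrees ends on the 90-degree antenna", {
  cfg <- sim_config(seed = 10, n_birds = c(CR = 1L, ER = 0L))
  cfg$signal$noise_sd_dB <- 0
  sim <- simulate_cohort(cfg)
  tr <- sim$truth
  tr$bearing <- 90
  stream <- simulate_detections(tr, cfg)
  expect_false(is.unsorted(as.numeric(stream$time)))
  last <- stream[which.max(as.numeric(stream$time)), ]
  expect_identical(last$antenna_id, "A090")
})

test_that("configuration files round-trip through YAML", {
  cfg <- sim_config(seed = 33)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_identical(simulate_cohort(back), simulate_cohort(cfg))
  unlink(f)
})
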