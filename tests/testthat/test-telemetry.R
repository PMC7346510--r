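ants12 <- data.frame(antenna_id = sprintf("A%03d", seq(0, 330, 30)),
                     bearing = seq(0, 330, 30), stringsAsFactors = FALSE)

# build an event + detections directly for bearing tests
bearing_of <- function(times, antennas, t0, t1, take_off = NULL,
                       ant_table = ants12, spacing = 30) {
  det <- data.frame(time = as.POSIXct(times, origin = "1970-01-01", tz = "UTC"),
                    antenna_id = antennas, signal = 50)
  ev <- list(event_start = as.POSIXct(t0, origin = "1970-01-01", tz = "UTC"),
             event_end = as.POSIXct(t1, origin = "1970-01-01", tz = "UTC"),
             take_off_time = as.POSIXct(if (is.null(take_off)) t0 else take_off,
                                        origin = "1970-01-01", tz = "UTC"),
             qc = character(0))
  estimate_bearing(ev, det, ant_table, spacing = spacing)
}

test_that("single-antenna and symmetric two-antenna events give exact bearings", {
  # all second-half detections on the 180-degree antenna
  b <- bearing_of(times = c(0, 300, 600, 900), antennas = rep("A180", 4),
                  t0 = 0, t1 = 900)
  expect_equal(b$bearing, 180)
  # equal weights on 150 and 210 average to 180
  b2 <- bearing_of(times = c(0, 600, 600), antennas = c("A180", "A150", "A210"),
                   t0 = 0, t1 = 1200)
  expect_equal(b2$bearing, 180)
})

test_that("bearing equals the brute-force weighted vector sum", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(2:6, 1)
    t1 <- 1200
    ts <- sort(runif(n, 0, t1))
    ants <- sample(ants12$antenna_id, n, replace = TRUE)
    res <- bearing_of(ts, ants, 0, t1)
    # oracle: same exclusion and linear-ramp weighting, naive summation
    mid <- t1 / 2
    keep <- ts >= mid
    if (!sum(keep)) next
    w <- (ts[keep] - mid) / (max(ts[keep]) - mid)
    if (all(w == 0)) w <- rep(1, sum(keep))
    expected <- brute_weighted_circ_mean(
      ants12$bearing[match(ants[keep], ants12$antenna_id)], w)
    if (!is.na(res$bearing)) expect_equal(res$bearing, expected, tolerance = 1e-9)
  }
})

test_that("bearing estimation is rotation equivariant", {
  ts <- c(100, 650, 800, 1150)
  ants <- c("A000", "A030", "A060", "A030")
  base <- bearing_of(ts, ants, 0, 1200)$bearing
  for (delta in c(40, 120, 275)) {
    rot <- ants12
    rot$bearing <- (rot$bearing + delta) %% 360
    shifted <- bearing_of(ts, ants, 0, 1200, ant_table = rot)$bearing
    expect_equal(shifted, (base + delta) %% 360, tolerance = 1e-9)
  }
})

test_that("events losing signal < 3 min after take-off are discarded", {
  det <- data.frame(time = as.POSIXct(c(0, 60, 120), origin = "1970-01-01", tz = "UTC"),
                    antenna_id = "A090", signal = 50)
  ev <- list(event_start = det$time[1], event_end = det$time[3],
             take_off_time = det$time[1], qc = "short_event")
  out <- estimate_bearing(ev, det, ants12)
  expect_true(is.na(out$bearing))
  expect_true("short_event" %in% out$qc)
})

test_that("a bearing with no pivotal antenna coverage is discarded", {
  # detections only on 30 and 150 with equal weight average to 90, but no
  # antenna of this sparse array points within 15 degrees of 90
  sparse <- data.frame(antenna_id = c("A030", "A150"), bearing = c(30, 150))
  out <- bearing_of(c(600, 600), c("A030", "A150"), 0, 1200, ant_table = sparse)
  expect_true(is.na(out$bearing))
  expect_true("pivotal_antenna_missing" %in% out$qc)
})

test_that("a flat stream that simply ceases yields no event", {
  t0 <- as.numeric(as.POSIXct("2018-09-02 20:00:00", tz = "UTC"))
  det <- data.frame(time = as.POSIXct(seq(t0, t0 + 3600, 10),
                                      origin = "1970-01-01", tz = "UTC"),
                    antenna_id = "A000", signal = 45)
  ev <- segment_departure_event(det)
  expect_identical(ev$qc, "no_event_found")
  expect_identical(segment_departure_event(det[0, ])$qc, "no_event_found")
})

test_that("with two surges, the terminal one defines the event", {
  t0 <- as.numeric(as.POSIXct("2018-09-02 20:00:00", tz = "UTC"))
  s1 <- make_departure_stream(t0 + 3600, decay_min = 10)
  # first surge, then signal returns to baseline, then the real departure
  mid <- data.frame(time = as.POSIXct(seq(t0 + 3600 + 601, t0 + 7200, 10),
                                      origin = "1970-01-01", tz = "UTC"),
                    tag_id = "T1", antenna_id = "A000", signal = 45)
  s2 <- make_departure_stream(t0 + 9000, pre_min = 25)
  det <- rbind(s1, mid, s2)
  ev <- segment_departure_event(det)
  expect_length(ev$qc, 0)
  expect_equal(as.numeric(ev$take_off_time), t0 + 9000)
})

test_that("noiseless simulated departures are recovered to one sample", {
  cfg <- sim_config(seed = 2, n_birds = c(CR = 4L, ER = 4L))
  cfg$signal$noise_sd_dB <- 0
  sim <- simulate_cohort(cfg)
  stream <- simulate_detections(sim$truth, cfg)
  ev <- detect_departures(stream, sim_antennas(cfg))
  tr <- sim$truth[match(ev$tag_id, sim$truth$tag_id), ]
  terr <- abs(as.numeric(ev$take_off_time) - as.numeric(tr$take_off_time))
  expect_true(all(terr <= cfg$signal$sampling_interval_s))
  derr <- abs((ev$bearing - tr$bearing + 180) %% 360 - 180)
  expect_true(all(derr[!is.na(derr)] <= 15))
})

test_that("minimum stopover counts nights inclusively", {
  cap <- as.Date("2018-09-02")
  expect_equal(minimum_stopover(cap, as.POSIXct("2018-09-02 21:10:00", tz = "UTC")), 1L)
  # after midnight, still the night following capture
  expect_equal(minimum_stopover(cap, as.POSIXct("2018-09-03 02:30:00", tz = "UTC")), 1L)
  expect_equal(minimum_stopover(cap, as.POSIXct("2018-09-18 22:00:00", tz = "UTC")), 17L)
  expect_error(minimum_stopover(cap, as.POSIXct("2018-09-01 22:00:00", tz = "UTC")),
               "precedes")
})

test_that("detection and antenna CSV round-trips preserve the stream", {
  cfg <- sim_config(seed = 6, n_birds = c(CR = 2L, ER = 1L))
  sim <- simulate_cohort(cfg)
  stream <- simulate_detections(sim$truth[1, , drop = FALSE], cfg)
  f <- tempfile(fileext = ".csv")
  write_detections(stream, f)
  back <- read_detections(f)
  expect_equal(as.numeric(back$time), round(as.numeric(stream$time)))
  expect_equal(back$antenna_id, stream$antenna_id)
  expect_equal(back$signal, stream$signal, tolerance = 1e-10)
  fa <- tempfile(fileext = ".csv")
  utils::write.csv(sim_antennas(cfg), fa, row.names = FALSE)
  expect_equal(read_antennas(fa)$bearing, seq(0, 330, 30))
  unlink(c(f, fa))
})
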