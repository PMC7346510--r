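# Synthetic telemetry streams and bird cohorts with known ground truth.
# The generator emulates the quasi-experimental Helgoland study design:
# one capture day per species, energy stores spanning -0.05..0.2 of lean
# body mass, first-night departure probability rising with (scaled) stores,
# nocturnal take-off timing beta-distributed on the proportion-of-night
# scale, and von Mises departure bearings; the radio layer is a 12-antenna
# 30-degree radial array with an inverse-square path loss and a cos^k
# boresight gain.

#' Simulation configuration
#'
#' Builds the parameter list for [simulate_cohort()] and
#' [simulate_detections()]. Defaults reproduce the study conditions: 14
#' common redstarts (CR) caught 2018-09-02 and 21 European robins (ER)
#' caught 2018-10-06 on Helgoland, energy stores uniform on
#' [-0.05, 0.2], first-night departure fractions near 43\% (CR) and
#' 33\% (ER) with the store effect present only in the redstarts, and
#' nocturnal timing drawn from the beta model with coefficients
#' intercept -1.20, species (ER) +1.15 and scaled-stores slope -0.45 on
#' the logit of proportion of night.
#'
#' @param n_birds named integer vector, birds per species.
#' @param species named list of per-species morphometric parameters:
#'   \code{wing_mean}, \code{wing_sd} (mm), \code{muscle_probs} (named
#'   probabilities over muscle scores, summing to 1),
#'   \code{capture_date}, \code{capture_hours_utc} (range),
#'   \code{dir_mean}, \code{dir_kappa} (von Mises bearing distribution),
#'   \code{dep_intercept}, \code{dep_slope} (logistic model of
#'   first-night departure on scaled stores), \code{wind_dir},
#'   \code{wind_speed} (constants attached to the bird table).
#' @param stores_range lower/upper bound of the uniform energy-store
#'   draw, as a fraction of lean body mass (lower bound > -1).
#' @param beta_coefs beta-regression generating coefficients
#'   (\code{intercept}, \code{species_ER}, \code{stores}) on the logit
#'   of proportion of night.
#' @param beta_phi beta precision of the timing distribution.
#' @param stay_geom_p geometric parameter for extra stopover nights of
#'   birds not departing on the first night (capped so the maximum
#'   stopover is \code{max_stopover_days}).
#' @param max_stopover_days cap on simulated minimum stopover duration.
#' @param site list with \code{lat}, \code{lon} of the stopover site.
#' @param signal radio-layer parameters: \code{antenna_bearings} (deg),
#'   \code{gain_exponent} (cos^k boresight pattern, in dB
#'   \code{10 k log10 cos}), \code{gain_floor_dB}, \code{ref_power_dB}
#'   (received at 1 m on boresight), \code{noise_sd_dB},
#'   \code{threshold_dB} (detection cut-off), \code{sampling_interval_s},
#'   \code{ground_speed_ms}, \code{ground_atten_dB} (extra loss while
#'   the bird sits on the ground), \code{ground_distance_m} (distance of
#'   the perch from the receiver), \code{pre_window_min} (length of the
#'   simulated stationary phase).
#' @param seed integer master seed; per-bird substreams are derived from
#'   it deterministically so that adding birds does not perturb earlier
#'   draws.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(
    n_birds = c(CR = 14L, ER = 21L),
    species = list(
      CR = list(wing_mean = 80, wing_sd = 2,
                muscle_probs = c(`2` = 1),
                capture_date = "2018-09-02", capture_hours_utc = c(6, 11),
                dir_mean = 232, dir_kappa = 5,
                dep_intercept = stats::qlogis(6 / 14), dep_slope = 1.5,
                wind_dir = 70, wind_speed = 7.5),
      ER = list(wing_mean = 72.5, wing_sd = 1.5,
                muscle_probs = c(`2` = 0.6, `3` = 0.4),
                capture_date = "2018-10-06", capture_hours_utc = c(9.5, 13),
                dir_mean = 185, dir_kappa = 25,
                dep_intercept = stats::qlogis(7 / 21), dep_slope = 0,
                wind_dir = 350, wind_speed = 6.6)),
    stores_range = c(-0.05, 0.2),
    beta_coefs = c(intercept = -1.20, species_ER = 1.15, stores = -0.45),
    beta_phi = 10,
    stay_geom_p = 0.25,
    max_stopover_days = 17L,
    site = list(lat = 54.1833, lon = 7.8833),
    signal = list(antenna_bearings = seq(0, 330, by = 30),
                  gain_exponent = 4, gain_floor_dB = -30,
                  ref_power_dB = 105, noise_sd_dB = 2,
                  threshold_dB = 20, sampling_interval_s = 5,
                  ground_speed_ms = 10, ground_atten_dB = 20,
                  ground_distance_m = 50, pre_window_min = 30),
    seed = 1L) {
  cfg <- list(n_birds = n_birds, species = species,
              stores_range = stores_range, beta_coefs = beta_coefs,
              beta_phi = beta_phi, stay_geom_p = stay_geom_p,
              max_stopover_days = as.integer(max_stopover_days),
              site = site, signal = signal, seed = as.integer(seed))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.validate_sim_config <- function(cfg) {
  if (cfg$stores_range[1] <= -1)
    stop("energy-store range lower bound must exceed -1")
  if (diff(cfg$stores_range) < 0) stop("stores_range must be non-decreasing")
  if (cfg$signal$sampling_interval_s <= 0) stop("sampling interval must be > 0")
  reg <- lean_mass_equations()
  for (sp in names(cfg$n_birds)) {
    p <- cfg$species[[sp]]
    if (is.null(p)) stop("no species parameters for ", sp)
    if (abs(sum(p$muscle_probs) - 1) > 1e-8)
      stop("muscle-score probabilities for ", sp, " must sum to 1")
    if (p$dir_kappa < 0) stop("von Mises concentration must be >= 0")
    scores <- as.integer(names(p$muscle_probs)[p$muscle_probs > 0])
    covered <- paste(sp, scores) %in% paste(reg$species, reg$muscle)
    if (!all(covered))
      stop("species/muscle combination without a lean-mass equation: ",
           paste(paste(sp, scores)[!covered], collapse = ", "))
  }
  invisible(cfg)
}

# deterministic per-bird substream seed (< 2^31)
.bird_seed <- function(master, i, salt = 0L) {
  (as.numeric(master) * 1009 + i * 7919 + salt * 104729) %% 2147483629
}

# von Mises sampler (Best & Fisher 1979 rejection scheme)
.rvonmises1 <- function(mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(1, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      th <- sign(u[3] - 0.5) * acos(f)
      return((mu_deg + th * 180 / pi) %% 360)
    }
  }
}

#' Simulate a bird cohort with known ground truth
#'
#' Draws one row per bird: morphometrics (wing length at 0.5 mm
#' resolution, muscle score, body mass = lean mass times 1 + e with e
#' the drawn energy stores — body mass is kept at full precision so the
#' energetics round-trip is exact), a first-night departure flag from
#' the per-species logistic model on within-species-scaled stores, the
#' departure night, the nocturnal take-off instant from the beta timing
#' model anchored to the site's actual sunset/sunrise, and a von Mises
#' departure bearing. All randomness comes from per-bird substreams
#' derived from \code{config$seed}.
#'
#' @param config a [sim_config()] list.
#' @return List with \code{birds} (data frame in the bird-table schema:
#'   \code{Time}, \code{Species}, \code{Muscle}, \code{Wing},
#'   \code{Bodymass}, \code{take.off}, \code{dep.dir},
#'   \code{days.on.island}, \code{dep.min.sunset},
#'   \code{dep.realtive.night}, \code{wind.speed}, \code{wind.dir},
#'   plus \code{tag_id}) and \code{truth} (data frame with
#'   \code{tag_id}, \code{species}, \code{energy_stores},
#'   \code{stores_scaled}, \code{departed_first_night},
#'   \code{take_off_time}, \code{bearing}).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config") || is.list(config))
  sp_names <- names(config$n_birds)
  draws <- list()
  idx <- 0L
  for (sp in sp_names) {
    p <- config$species[[sp]]
    for (j in seq_len(config$n_birds[[sp]])) {
      idx <- idx + 1L
      set.seed(.bird_seed(config$seed, idx))
      wing <- round(stats::rnorm(1, p$wing_mean, p$wing_sd) * 2) / 2
      wing <- max(wing, 1)
      muscle <- as.integer(sample(names(p$muscle_probs), 1,
                                  prob = p$muscle_probs))
      e <- stats::runif(1, config$stores_range[1], config$stores_range[2])
      u_dep <- stats::runif(1)
      u_beta <- stats::runif(1)
      extra_nights <- min(stats::rgeom(1, config$stay_geom_p) + 1L,
                          config$max_stopover_days - 1L)
      bearing <- .rvonmises1(p$dir_mean, p$dir_kappa)
      cap_h <- stats::runif(1, p$capture_hours_utc[1], p$capture_hours_utc[2])
      draws[[idx]] <- data.frame(
        tag_id = sprintf("%s%02d", sp, j), species = sp,
        wing = wing, muscle = muscle, e = e, u_dep = u_dep,
        u_beta = u_beta, extra_nights = extra_nights, bearing = bearing,
        capture_hour = cap_h, stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, draws)

  lean <- lean_body_mass(d$species, d$muscle, d$wing)
  body <- lean * (1 + d$e)
  # within-species z-scores of the drawn stores; degenerate draws (single
  # bird, or a point-mass store range) contribute a zero store effect
  e_scaled <- numeric(nrow(d))
  for (sp in unique(d$species)) {
    i <- which(d$species == sp)
    s <- stats::sd(d$e[i])
    e_scaled[i] <- if (length(i) < 2 || !is.finite(s) || s == 0) 0
    else (d$e[i] - mean(d$e[i])) / s
  }

  sp_par <- config$species[d$species]
  dep_p <- stats::plogis(
    vapply(sp_par, function(p) p$dep_intercept, numeric(1)) +
      vapply(sp_par, function(p) p$dep_slope, numeric(1)) * e_scaled)
  first_night <- d$u_dep < dep_p
  days <- ifelse(first_night, 1L, 1L + d$extra_nights)

  b <- config$beta_coefs
  mu <- stats::plogis(b[["intercept"]] +
                        b[["species_ER"]] * (d$species == "ER") +
                        b[["stores"]] * e_scaled)
  prop_night <- stats::qbeta(d$u_beta, mu * config$beta_phi,
                             (1 - mu) * config$beta_phi)

  capture_date <- as.Date(vapply(sp_par, function(p) p$capture_date, ""))
  night_date <- capture_date + days - 1L
  take_off <- as.POSIXct(rep(NA_real_, nrow(d)), origin = "1970-01-01", tz = "UTC")
  mins_sunset <- numeric(nrow(d))
  for (i in seq_len(nrow(d))) {
    ev <- sun_events(night_date[i], config$site$lat, config$site$lon)
    night_len <- as.numeric(difftime(ev$next_sunrise, ev$sunset, units = "mins"))
    mins_sunset[i] <- prop_night[i] * night_len
    take_off[i] <- ev$sunset + 60 * mins_sunset[i]
  }

  birds <- data.frame(
    tag_id = d$tag_id,
    Time = format(as.POSIXct(paste(capture_date, "00:00:00"), tz = "UTC") +
                    3600 * d$capture_hour, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    Species = d$species, Muscle = d$muscle, Wing = d$wing, Bodymass = body,
    take.off = format(take_off, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    dep.dir = d$bearing, days.on.island = days,
    dep.min.sunset = mins_sunset, dep.realtive.night = prop_night,
    wind.speed = vapply(sp_par, function(p) p$wind_speed, numeric(1)),
    wind.dir = vapply(sp_par, function(p) p$wind_dir, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(birds) <- NULL
  truth <- data.frame(
    tag_id = d$tag_id, species = d$species, energy_stores = d$e,
    stores_scaled = e_scaled, departed_first_night = first_night,
    take_off_time = take_off, bearing = d$bearing, capture_date = capture_date,
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(birds = birds, truth = truth)
}

#' Simulate a multi-antenna detection stream
#'
#' Produces the raw telemetry pings implied by a ground truth: each bird
#' sits at a perch near the receiver during a stationary phase (extra
#' ground attenuation), becomes airborne at its true take-off time (the
#' attenuation drops, so the received signal surges and is maximal at
#' take-off), then flies a straight line at constant ground speed along
#' its true bearing until the path loss pushes every antenna below the
#' detection threshold. The received strength per antenna is
#' \eqn{P_0 - 20\log_{10}(d) + G(\delta) + noise} with
#' \eqn{G(\delta) = \max(10 k \log_{10}\cos\delta, floor)} the boresight
#' gain at angular offset \eqn{\delta}. Birds that never depart emit
#' only the stationary phase (their stream simply ceases). The stream is
#' time-sorted.
#'
#' @param truth ground-truth data frame from [simulate_cohort()] (only
#'   \code{tag_id}, \code{take_off_time}, \code{bearing} and
#'   \code{departed_first_night} are used; birds with \code{NA}
#'   take-off are treated as non-departing).
#' @param config a [sim_config()] list.
#' @return Data frame with columns \code{time} (POSIXct UTC),
#'   \code{tag_id}, \code{antenna_id}, \code{signal} (dB).
#' @export
simulate_detections <- function(truth, config = sim_config()) {
  sg <- config$signal
  ant_bear <- sg$antenna_bearings %% 360
  ant_id <- sprintf("A%03d", round(ant_bear))
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    set.seed(.bird_seed(config$seed, i, salt = 1L))
    t0 <- as.numeric(truth$take_off_time[i])
    departing <- !is.na(t0)
    if (!departing) t0 <- as.numeric(as.POSIXct(truth$capture_date[i],
                                                tz = "UTC")) + 20 * 3600
    theta_g <- stats::runif(1, 0, 360)
    d0 <- sg$ground_distance_m
    pg <- d0 * c(sin(theta_g * pi / 180), cos(theta_g * pi / 180)) # (E, N)

    pre_t <- seq(t0 - sg$pre_window_min * 60, t0 - sg$sampling_interval_s,
                 by = sg$sampling_interval_s)
    if (departing) {
      d_max <- 10^((sg$ref_power_dB - sg$threshold_dB + 5) / 20)
      dur <- min((d_max + d0) / sg$ground_speed_ms, 3600)
      fly_t <- seq(t0, t0 + dur, by = sg$sampling_interval_s)
    } else fly_t <- numeric(0)

    times <- c(pre_t, fly_t)
    n_pre <- length(pre_t)
    u <- c(sin(truth$bearing[i] * pi / 180), cos(truth$bearing[i] * pi / 180))
    ex <- c(rep(pg[1], n_pre), pg[1] + u[1] * sg$ground_speed_ms * (fly_t - t0))
    ny <- c(rep(pg[2], n_pre), pg[2] + u[2] * sg$ground_speed_ms * (fly_t - t0))
    dist <- pmax(sqrt(ex^2 + ny^2), 1)
    azim <- (atan2(ex, ny) * 180 / pi) %% 360
    grounded <- c(rep(sg$ground_atten_dB, n_pre), rep(0, length(fly_t)))

    # all times x antennas
    nt <- length(times); na <- length(ant_bear)
    off <- abs((rep(azim, times = na) - rep(ant_bear, each = nt) + 180) %% 360 - 180)
    cosoff <- pmax(cos(off * pi / 180), 1e-12)
    gain <- pmax(10 * sg$gain_exponent * log10(cosoff), sg$gain_floor_dB)
    sig <- sg$ref_power_dB - 20 * log10(rep(dist, times = na)) + gain -
      rep(grounded, times = na) +
      stats::rnorm(nt * na, 0, sg$noise_sd_dB)
    keep <- sig >= sg$threshold_dB
    if (!any(keep)) next
    out[[i]] <- data.frame(
      time = as.POSIXct(rep(times, times = na)[keep],
                        origin = "1970-01-01", tz = "UTC"),
      tag_id = truth$tag_id[i],
      antenna_id = rep(ant_id, each = nt)[keep],
      signal = sig[keep], stringsAsFactors = FALSE)
  }
  stream <- do.call(rbind, out)
  stream <- stream[order(stream$time, stream$tag_id, stream$antenna_id), ]
  rownames(stream) <- NULL
  stream
}

#' Antenna table matching a simulation configuration
#'
#' @param config a [sim_config()] list.
#' @param site site identifier for the \code{site} column.
#' @return Data frame with \code{antenna_id}, \code{site},
#'   \code{bearing}.
#' @export
sim_antennas <- function(config = sim_config(), site = "S1") {
  b <- config$signal$antenna_bearings %% 360
  data.frame(antenna_id = sprintf("A%03d", round(b)), site = site,
             bearing = b, stringsAsFactors = FALSE)
}

#' Write / read a simulation configuration as a YAML file
#'
#' @param config a [sim_config()] list.
#' @param file path to the YAML file.
#' @return \code{read_sim_config} returns a validated
#'   \code{"sim_config"} list.
#' @export
write_sim_config <- function(config, file) {
  cfg <- unclass(config)
  # named atomic vectors serialise as YAML maps only as lists
  cfg$n_birds <- as.list(cfg$n_birds)
  cfg$beta_coefs <- as.list(cfg$beta_coefs)
  for (sp in names(cfg$species))
    cfg$species[[sp]]$muscle_probs <- as.list(cfg$species[[sp]]$muscle_probs)
  yaml::write_yaml(cfg, file)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  cfg$n_birds <- unlist(cfg$n_birds)
  cfg$beta_coefs <- unlist(cfg$beta_coefs)
  cfg$stores_range <- as.numeric(unlist(cfg$stores_range))
  for (sp in names(cfg$species)) {
    cfg$species[[sp]]$muscle_probs <- unlist(cfg$species[[sp]]$muscle_probs)
    cfg$species[[sp]]$capture_hours_utc <-
      as.numeric(unlist(cfg$species[[sp]]$capture_hours_utc))
  }
  cfg$signal$antenna_bearings <- as.numeric(unlist(cfg$signal$antenna_bearings))
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}
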