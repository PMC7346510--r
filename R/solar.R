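# NOAA solar position algorithm (the one behind the NOAA sunrise/sunset
# calculator). Accuracy of the computed event times is about +/- 1-2 min at
# mid latitudes, ample for telemetry work referenced to sunset.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Solar declination (deg) and equation of time (min) at a Julian-century epoch
.solar_decl_eot <- function(t) {
  L0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  M <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  C <- sin(deg2rad(M)) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(deg2rad(2 * M)) * (0.019993 - 0.000101 * t) +
    sin(deg2rad(3 * M)) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * t
  app_long <- true_long - 0.00569 - 0.00478 * sin(deg2rad(omega))
  obl0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  obl <- obl0 + 0.00256 * cos(deg2rad(omega))
  decl <- rad2deg(asin(sin(deg2rad(obl)) * sin(deg2rad(app_long))))
  y <- tan(deg2rad(obl / 2))^2
  eot <- 4 * rad2deg(
    y * sin(2 * deg2rad(L0)) -
      2 * ecc * sin(deg2rad(M)) +
      4 * ecc * y * sin(deg2rad(M)) * cos(2 * deg2rad(L0)) -
      0.5 * y^2 * sin(4 * deg2rad(L0)) -
      1.25 * ecc^2 * sin(2 * deg2rad(M))
  )
  list(decl = decl, eot = eot)
}

# Hour angle (deg) of the sun at the given zenith; NA under polar conditions
.hour_angle <- function(lat, decl, zenith) {
  cos_ha <- (cos(deg2rad(zenith)) -
               sin(deg2rad(lat)) * sin(deg2rad(decl))) /
    (cos(deg2rad(lat)) * cos(deg2rad(decl)))
  if (cos_ha < -1 || cos_ha > 1) return(NA_real_)
  rad2deg(acos(cos_ha))
}

# One sunrise/sunset event, minutes after 0h UTC; two-pass refinement of the
# declination/equation-of-time epoch
.sun_event_minutes <- function(jd0, lat, lon, zenith, rising) {
  minutes <- 720 # start the iteration at 12:00 UTC
  for (pass in 1:2) {
    t <- (jd0 + minutes / 1440 - 2451545) / 36525
    se <- .solar_decl_eot(t)
    ha <- .hour_angle(lat, se$decl, zenith)
    if (is.na(ha))
      stop("polar day/night: sun does not cross the requested zenith at ",
           "latitude ", lat, " on this date")
    noon <- 720 - 4 * lon - se$eot
    minutes <- if (rising) noon - 4 * ha else noon + 4 * ha
  }
  minutes
}

#' Sunrise and sunset for a site
#'
#' Computes the sunrise and sunset instants (UTC) of a calendar date at a
#' given location with the NOAA solar position algorithm. The default
#' zenith of 90.833 degrees is the standard "official" sunrise/sunset
#' convention (atmospheric refraction plus the solar radius), matching
#' published sunrise/sunset tables to within about two minutes.
#'
#' @param date a \code{Date} (or something coercible), interpreted as the
#'   UTC calendar date.
#' @param lat,lon site latitude/longitude in decimal degrees (east and
#'   north positive). Latitudes within the polar circles raise an error
#'   on dates with midnight sun or polar night.
#' @param zenith solar zenith angle defining the event, degrees.
#' @return A list with \code{POSIXct} (UTC) elements \code{sunrise} and
#'   \code{sunset} for that date, and \code{next_sunrise}, the sunrise of
#'   the following date (the end of the night that starts at
#'   \code{sunset}).
#' @examples
#' sun_events(as.Date("2018-09-02"), lat = 54.1833, lon = 7.8833)
#' @export
sun_events <- function(date, lat, lon, zenith = 90.833) {
  date <- as.Date(date)
  if (length(date) != 1) stop("one date at a time")
  jd0 <- as.numeric(date) + 2440587.5 # Julian day at 0h UTC
  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  mins <- function(jd, rising) .sun_event_minutes(jd, lat, lon, zenith, rising)
  list(
    sunrise = day0 + 60 * mins(jd0, TRUE),
    sunset = day0 + 60 * mins(jd0, FALSE),
    next_sunrise = day0 + 86400 + 60 * mins(jd0 + 1, TRUE)
  )
}

#' Express a take-off instant relative to the night
#'
#' Finds the night (local sunset to next sunrise) containing a take-off
#' and returns the departure time as minutes after sunset and as the
#' proportion of the night elapsed. The proportion normalises for the
#' seasonal change in night length, so departures from different dates
#' are comparable. Take-offs in daylight are flagged \code{diurnal} and
#' get an undefined (NA) proportion.
#'
#' @param take_off a \code{POSIXct} instant (any time zone; converted to
#'   UTC internally).
#' @param lat,lon site coordinates, decimal degrees.
#' @param zenith solar zenith defining sunset/sunrise, degrees.
#' @return A one-row data frame with columns \code{sunset},
#'   \code{next_sunrise} (POSIXct UTC), \code{night_length} (min),
#'   \code{minutes_after_sunset}, \code{proportion_of_night} and
#'   \code{diurnal} (logical).
#' @export
night_timing <- function(take_off, lat, lon, zenith = 90.833) {
  if (length(take_off) != 1) stop("one take-off at a time")
  take_off <- as.POSIXct(take_off)
  attr(take_off, "tzone") <- "UTC"
  d <- as.Date(take_off, tz = "UTC")
  ev <- sun_events(d, lat, lon, zenith)
  if (take_off < ev$sunset) { # belongs to the night that began the day before
    ev <- sun_events(d - 1, lat, lon, zenith)
  }
  night_length <- as.numeric(difftime(ev$next_sunrise, ev$sunset, units = "mins"))
  mins <- as.numeric(difftime(take_off, ev$sunset, units = "mins"))
  diurnal <- take_off < ev$sunset || take_off > ev$next_sunrise
  data.frame(
    sunset = ev$sunset,
    next_sunrise = ev$next_sunrise,
    night_length = night_length,
    minutes_after_sunset = mins,
    proportion_of_night = if (diurnal) NA_real_ else mins / night_length,
    diurnal = diurnal
  )
}
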