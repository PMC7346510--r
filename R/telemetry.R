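# Departure-event detection from multi-antenna radio-telemetry streams.
# A departure shows up as a rapid surge in signal strength on most antennas
# (the bird leaves the ground and clears the local clutter), a peak near the
# take-off instant, then a decline on fewer and fewer antennas until the
# signal is permanently lost as the bird leaves the survey volume.

#' Default detection parameters
#'
#' @param rise_dB minimum rise of the across-antenna aggregate signal over
#'   the trailing baseline that marks a take-off (dB).
#' @param rise_window_min lag (minutes) between the trailing-baseline
#'   window and the point being tested; the surge must happen within it.
#' @param baseline_win_min length (minutes) of the trailing window whose
#'   median defines the pre-departure baseline.
#' @param gap_min a silence of at least this many minutes after the event
#'   counts as permanent signal loss.
#' @param min_event_min events in which the signal is lost less than this
#'   many minutes after take-off are too short to yield a trustworthy
#'   bearing and are discarded (flag \code{short_event}).
#' @return Named list of parameters.
#' @export
departure_params <- function(rise_dB = 10, rise_window_min = 10,
                             baseline_win_min = 30, gap_min = 30,
                             min_event_min = 3) {
  list(rise_dB = rise_dB, rise_window_min = rise_window_min,
       baseline_win_min = baseline_win_min, gap_min = gap_min,
       min_event_min = min_event_min)
}

#' Segment the terminal departure event of one tag
#'
#' Scans a time-sorted detection stream of a single tag for the terminal
#' departure signature: the across-antenna maximum signal rising by at
#' least \code{rise_dB} above its trailing baseline, peaking, and then
#' declining into permanent signal loss. The take-off time is the time
#' of the single highest signal strength inside the event (earliest on
#' ties). Streams that simply cease without this shape yield no event
#' (\code{no_event_found}); when several surges exist the final one
#' (the one followed by permanent loss) is taken.
#'
#' @param det data frame with columns \code{time} (POSIXct), \code{antenna_id}
#'   and \code{signal} (dB-like, monotone in received power), one tag only.
#' @param params list from [departure_params()].
#' @return A list with \code{event_start}, \code{event_end},
#'   \code{take_off_time} (POSIXct) and \code{qc} (character vector of
#'   flags), or a list with only \code{qc = "no_event_found"}.
#' @export
segment_departure_event <- function(det, params = departure_params()) {
  if (is.null(det) || nrow(det) == 0)
    return(list(qc = "no_event_found"))
  det <- det[order(det$time), , drop = FALSE]
  # across-antenna aggregate: max signal per timestamp
  t_num <- as.numeric(det$time)
  tt <- unique(t_num) # det is time-sorted, so tt is too
  s <- as.numeric(tapply(det$signal, match(t_num, tt), max))
  m <- length(s)
  if (m < 2) return(list(qc = "no_event_found"))

  lag <- params$rise_window_min * 60
  bw <- params$baseline_win_min * 60
  # trailing baseline: median aggregate signal in [t - lag - bw, t - lag]
  base <- vapply(seq_len(m), function(i) {
    j <- which(tt >= tt[i] - lag - bw & tt <= tt[i] - lag)
    if (!length(j)) NA_real_ else stats::median(s[j])
  }, numeric(1))
  over <- !is.na(base) & s >= base + params$rise_dB
  if (!any(over)) return(list(qc = "no_event_found"))
  # runs above threshold; runs separated by a short dip (noise flicker around
  # the crossing) belong to the same surge, so merge before picking the final
  onset_idx <- which(over & !c(FALSE, over[-m]))
  end_idx <- which(over & !c(over[-1], FALSE))
  keep_new <- c(TRUE, tt[onset_idx[-1]] - tt[end_idx[-length(end_idx)]] >=
                  params$rise_window_min * 60)
  onset_idx <- onset_idx[keep_new]
  start_i <- onset_idx[length(onset_idx)]
  t_start <- tt[start_i]

  # truncate at the first silence >= gap_min after onset (anything beyond is
  # not part of the terminal loss)
  after <- which(tt >= t_start)
  gaps <- diff(tt[after])
  cut <- which(gaps >= params$gap_min * 60)
  end_i <- if (length(cut)) after[cut[1]] else after[length(after)]
  t_end <- tt[end_i]

  win <- which(tt >= t_start & tt <= t_end)
  peak_i <- win[which.max(s[win])] # which.max: earliest index on ties
  qc <- character(0)
  if (t_end - tt[peak_i] < params$min_event_min * 60) qc <- "short_event"
  list(
    event_start = det$time[match(t_start, t_num)],
    event_end = det$time[match(t_end, t_num)],
    take_off_time = det$time[match(tt[peak_i], t_num)],
    qc = qc
  )
}

#' Weighted circular-mean departure bearing of an event
#'
#' Estimates the vanishing bearing as a weighted circular mean of the
#' boresight directions of the antennas that received the signal.
#' Only detections from the second half of the event window (time axis)
#' are used, which suppresses misleading hits on antenna back and side
#' lobes around take-off; each detection's antenna bearing enters with
#' weight \eqn{w_i = (t_i - t_{mid})/(t_{last} - t_{mid})}, a linear
#' ramp in temporal proximity to the last detection. The bearing is
#' discarded (returned \code{NA}) with a QC flag when the event is
#' shorter than the trustworthy minimum after take-off
#' (\code{short_event}) or when no antenna aligned close to the result
#' recorded anything during the event (\code{pivotal_antenna_missing}).
#'
#' @param event event list from [segment_departure_event()].
#' @param det detection data frame of the same tag (columns \code{time},
#'   \code{antenna_id}, \code{signal}).
#' @param antennas data frame with columns \code{antenna_id} and
#'   \code{bearing} (degrees in [0, 360)).
#' @param spacing angular spacing of the antenna array in degrees; an
#'   antenna within \code{spacing/2} of the computed bearing counts as
#'   pivotal.
#' @param params list from [departure_params()].
#' @return List with \code{bearing} (degrees in [0, 360) or NA) and
#'   \code{qc} flags.
#' @export
estimate_bearing <- function(event, det, antennas, spacing = 30,
                             params = departure_params()) {
  if ("no_event_found" %in% event$qc)
    return(list(bearing = NA_real_, qc = event$qc))
  qc <- event$qc
  if ("short_event" %in% qc)
    return(list(bearing = NA_real_, qc = qc))
  t0 <- as.numeric(event$event_start)
  t1 <- as.numeric(event$event_end)
  dd <- det[as.numeric(det$time) >= t0 & as.numeric(det$time) <= t1, , drop = FALSE]
  t_mid <- t0 + (t1 - t0) / 2
  second <- dd[as.numeric(dd$time) >= t_mid, , drop = FALSE]
  if (nrow(second) == 0)
    return(list(bearing = NA_real_, qc = c(qc, "no_second_half_detections")))
  br <- antennas$bearing[match(second$antenna_id, antennas$antenna_id)]
  if (anyNA(br))
    stop("detections reference antennas absent from the antenna table: ",
         paste(unique(second$antenna_id[is.na(br)]), collapse = ", "))
  ti <- as.numeric(second$time)
  t_last <- max(ti)
  w <- if (t_last > t_mid) (ti - t_mid) / (t_last - t_mid) else rep(1, length(ti))
  if (all(w == 0)) w <- rep(1, length(ti)) # single detection exactly at midpoint
  bearing <- circ_mean_rho(br, w)$mean

  # pivotal-antenna check: some antenna pointing near the result must have
  # recorded signal during the event
  ev_br <- antennas$bearing[match(dd$antenna_id, antennas$antenna_id)]
  delta <- abs((ev_br - bearing + 180) %% 360 - 180)
  if (!any(delta <= spacing / 2)) {
    return(list(bearing = NA_real_, qc = c(qc, "pivotal_antenna_missing")))
  }
  list(bearing = bearing, qc = qc)
}

#' Minimum stopover duration in days
#'
#' Calendar days from the capture day to the departure night, inclusive;
#' a bird departing during the night that follows its capture day scores
#' 1. Take-offs after midnight still belong to the previous evening's
#' night (noon-to-noon convention in UTC). This is a lower bound on the
#' true stopover because arrival precedes capture.
#'
#' @param capture_date \code{Date} of capture.
#' @param take_off_time \code{POSIXct} departure instant (UTC).
#' @return Integer number of days (>= 1).
#' @export
minimum_stopover <- function(capture_date, take_off_time) {
  capture_date <- as.Date(capture_date)
  take_off_time <- as.POSIXct(take_off_time)
  attr(take_off_time, "tzone") <- "UTC"
  if (as.numeric(take_off_time) <=
      as.numeric(as.POSIXct(paste(format(capture_date), "00:00:00"), tz = "UTC")))
    stop("take-off precedes the capture day")
  # departure-night date: the date whose evening the night belongs to
  night_date <- as.Date(as.numeric(take_off_time - 12 * 3600) / 86400,
                        origin = "1970-01-01")
  days <- as.integer(night_date - capture_date) + 1L
  if (days < 1L) stop("take-off precedes the capture day")
  days
}

#' Detect departures for every tag in a detection stream
#'
#' Convenience wrapper running [segment_departure_event()] and
#' [estimate_bearing()] per tag and assembling one row per tag.
#'
#' @param stream detection data frame (\code{time}, \code{tag_id},
#'   \code{antenna_id}, \code{signal}).
#' @param antennas antenna table (\code{antenna_id}, \code{bearing}).
#' @param capture_dates optional named vector/list of capture
#'   \code{Date}s per tag_id; when given, minimum stopover duration is
#'   added.
#' @param spacing antenna array spacing in degrees.
#' @param params list from [departure_params()].
#' @return Data frame with one row per tag: \code{tag_id},
#'   \code{event_start}, \code{event_end}, \code{take_off_time},
#'   \code{bearing}, \code{qc} (comma-joined flags) and, if capture
#'   dates were supplied, \code{min_stopover_days}.
#' @export
detect_departures <- function(stream, antennas, capture_dates = NULL,
                              spacing = 30, params = departure_params()) {
  tags <- unique(stream$tag_id)
  rows <- lapply(tags, function(tg) {
    det <- stream[stream$tag_id == tg, , drop = FALSE]
    ev <- segment_departure_event(det, params)
    if ("no_event_found" %in% ev$qc) {
      return(data.frame(tag_id = tg, event_start = as.POSIXct(NA),
                        event_end = as.POSIXct(NA), take_off_time = as.POSIXct(NA),
                        bearing = NA_real_, qc = "no_event_found",
                        stringsAsFactors = FALSE))
    }
    be <- estimate_bearing(ev, det, antennas, spacing, params)
    data.frame(tag_id = tg, event_start = ev$event_start,
               event_end = ev$event_end, take_off_time = ev$take_off_time,
               bearing = be$bearing,
               qc = paste(be$qc, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(capture_dates)) {
    cd <- capture_dates[match(out$tag_id, names(capture_dates))]
    out$min_stopover_days <- ifelse(
      is.na(out$take_off_time), NA_integer_,
      mapply(function(c, t) if (is.na(t)) NA_integer_ else
        minimum_stopover(as.Date(c, origin = "1970-01-01"),
                         as.POSIXct(t, origin = "1970-01-01", tz = "UTC")),
        cd, as.numeric(out$take_off_time)))
  }
  out
}

#' Read a detection stream CSV
#'
#' Expects a comma-separated file with a header row and columns
#' \code{ts} (ISO-8601 UTC), \code{tag_id}, \code{antenna_id},
#' \code{sig_dB}, the dialect written by [write_detections()].
#'
#' @param file path to the CSV.
#' @return Data frame with columns \code{time} (POSIXct UTC),
#'   \code{tag_id}, \code{antenna_id}, \code{signal}.
#' @export
read_detections <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("ts", "tag_id", "antenna_id", "sig_dB")
  if (!all(need %in% names(d)))
    stop("detection CSV must have columns: ", paste(need, collapse = ", "))
  data.frame(time = as.POSIXct(d$ts, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")),
             tag_id = d$tag_id, antenna_id = d$antenna_id,
             signal = d$sig_dB, stringsAsFactors = FALSE)
}

#' Write a detection stream CSV
#'
#' @param stream detection data frame as returned by
#'   [simulate_detections()] or [read_detections()].
#' @param file output path.
#' @export
write_detections <- function(stream, file) {
  utils::write.csv(data.frame(
    ts = format(stream$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    tag_id = stream$tag_id, antenna_id = stream$antenna_id,
    sig_dB = stream$signal), file, row.names = FALSE, quote = FALSE)
}

#' Read an antenna configuration CSV
#'
#' Columns: \code{antenna_id}, \code{site}, \code{bearing} (degrees).
#'
#' @param file path to the CSV.
#' @return Data frame of antennas.
#' @export
read_antennas <- function(file) {
  a <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("antenna_id", "bearing") %in% names(a)))
    stop("antenna CSV must have columns antenna_id and bearing")
  a$bearing <- a$bearing %% 360
  a
}
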