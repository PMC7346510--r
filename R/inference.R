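# Regression and non-parametric inference linking energy stores to the
# three components of the departure decision, plus the end-to-end study
# pipeline over a bird table.

#' Normal linear regression with the reporting used for timing models
#'
#' Ordinary least squares via \code{\link[stats]{lm}}, optionally on the
#' log10-transformed response (the convention for minutes-after-sunset
#' departure timing, whose residuals are right-skewed on the raw scale).
#'
#' @param formula model formula.
#' @param data data frame.
#' @param log10_response transform the response with log10 before
#'   fitting.
#' @return List of class \code{"linear_fit"}: \code{coefficients}
#'   (matrix with estimate, SE, t, p), \code{r_squared}, \code{f},
#'   \code{df} (length 2), \code{p_overall}, \code{n}, and the
#'   underlying \code{lm} object as \code{fit}.
#' @export
fit_linear_model <- function(formula, data, log10_response = FALSE) {
  if (log10_response) {
    mf <- stats::model.frame(formula, data)
    y <- stats::model.response(mf)
    if (any(y <= 0)) stop("log10 transform needs a positive response")
    data[[as.character(formula[[2]])]] <- log10(y)
  }
  fit <- stats::lm(formula, data)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = sm$coefficients,
    r_squared = sm$r.squared,
    f = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df = if (is.null(fstat)) c(NA, NA) else unname(fstat[2:3]),
    p_overall = if (is.null(fstat)) NA_real_ else
      unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = length(stats::residuals(fit)),
    log10_response = log10_response,
    fit = fit
  ), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat("Linear model", if (x$log10_response) "(log10 response)", ", n =", x$n, "\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("R2 =", format(x$r_squared, digits = 3),
      " F(", x$df[1], ",", x$df[2], ") =", format(x$f, digits = 3),
      " p =", format(x$p_overall, digits = 3), "\n")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Wraps \code{\link[stats]{wilcox.test}} with the convention under
#' which published W statistics are reproducible: W counts the pairs
#' (a_i, b_j) with a_i > b_j (plus half the ties). The p-value is exact
#' for small untied samples and a normal approximation with continuity
#' correction otherwise.
#'
#' @param a,b numeric samples.
#' @return List with \code{W}, \code{p}, \code{n} (c(n_a, n_b)).
#' @export
mann_whitney <- function(a, b) {
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, n = c(length(a), length(b)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p summing the hypergeometric probabilities of all
#' tables (with the observed margins) no more probable than the
#' observed one; wraps \code{\link[stats]{fisher.test}}.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative integers")
  stats::fisher.test(tab)$p.value
}

#' Read an hourly weather CSV
#'
#' Expects columns \code{ts} (ISO-8601 UTC, on the full hour),
#' \code{wind_speed} (m/s), \code{wind_dir} (degrees, meteorological:
#' the direction the wind blows from), \code{precip} (mm), \code{temp}
#' (deg C).
#'
#' @param file path.
#' @return Data frame with \code{time} (POSIXct UTC) and the four
#'   weather columns.
#' @export
read_weather <- function(file) {
  w <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("ts", "wind_speed", "wind_dir", "precip", "temp")
  if (!all(need %in% names(w)))
    stop("weather CSV must have columns: ", paste(need, collapse = ", "))
  data.frame(time = as.POSIXct(w$ts, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")),
             wind_speed = w$wind_speed, wind_dir = w$wind_dir %% 360,
             precip = w$precip, temp = w$temp, stringsAsFactors = FALSE)
}

#' Weather at sunset for a run of dates
#'
#' For each calendar date, computes the site's sunset, rounds it to the
#' nearest full hour, and picks the hourly weather row closest to that
#' hour (within +/- 3 h; otherwise the row is flagged missing). Wind
#' direction stays meteorological (blowing from); the blowing-toward
#' direction (direction + 180 mod 360) is added for plotting against
#' departure bearings.
#'
#' @param dates vector of \code{Date}s.
#' @param weather data frame from [read_weather()].
#' @param lat,lon site coordinates.
#' @return Data frame with one row per date: \code{date},
#'   \code{sunset_hour} (POSIXct UTC), \code{wind_speed},
#'   \code{wind_dir}, \code{wind_toward}, \code{precip}, \code{temp},
#'   \code{missing} (logical).
#' @export
attach_weather <- function(dates, weather, lat, lon) {
  dates <- as.Date(dates)
  rows <- lapply(dates, function(d) {
    ss <- sun_events(d, lat, lon)$sunset
    hour <- as.POSIXct(round(as.numeric(ss) / 3600) * 3600,
                       origin = "1970-01-01", tz = "UTC")
    gap <- abs(as.numeric(weather$time) - as.numeric(hour))
    i <- which.min(gap)
    if (!length(i) || gap[i] > 3 * 3600) {
      return(data.frame(date = d, sunset_hour = hour, wind_speed = NA_real_,
                        wind_dir = NA_real_, wind_toward = NA_real_,
                        precip = NA_real_, temp = NA_real_, missing = TRUE))
    }
    data.frame(date = d, sunset_hour = hour,
               wind_speed = weather$wind_speed[i],
               wind_dir = weather$wind_dir[i],
               wind_toward = (weather$wind_dir[i] + 180) %% 360,
               precip = weather$precip[i], temp = weather$temp[i],
               missing = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a bird table CSV
#'
#' Reads the capture/departure table (columns \code{Time},
#' \code{Species}, \code{Muscle}, \code{Wing}, \code{Bodymass},
#' \code{take.off}, \code{dep.dir}, \code{days.on.island},
#' \code{dep.min.sunset}, \code{dep.realtive.night}, \code{wind.speed},
#' \code{wind.dir}). Both the historical misspelling
#' \code{dep.realtive.night} and the corrected
#' \code{dep.relative.night} are accepted; the column is normalised to
#' \code{dep.relative.night}.
#'
#' @param file path to the CSV.
#' @return Data frame with the normalised schema.
#' @export
read_bird_table <- function(file) {
  b <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if ("dep.realtive.night" %in% names(b) && !"dep.relative.night" %in% names(b))
    names(b)[names(b) == "dep.realtive.night"] <- "dep.relative.night"
  need <- c("Species", "Muscle", "Wing", "Bodymass", "days.on.island")
  if (!all(need %in% names(b)))
    stop("bird table must have at least columns: ", paste(need, collapse = ", "))
  b
}

.get_col <- function(birds, ...) {
  for (nm in c(...)) if (nm %in% names(birds)) return(birds[[nm]])
  NULL
}

#' Run the full stopover-departure analysis on a bird table
#'
#' End-to-end pipeline mirroring the study's Results: derives lean body
#' mass, energy stores and within-species scaled stores from the
#' morphometrics; splits first-night departers from stayers; and runs
#' the species comparison of stores (linear model), the stopover
#' comparison and the per-species departer-vs-stayer store comparisons
#' (Mann-Whitney), the departure-fraction contrast (Fisher's exact
#' test), the beta regressions on proportion of night (all birds:
#' species; first night: species + scaled stores), the normal linear
#' models on log10 minutes after sunset (same two designs), the
#' redstart-only first-night minutes model, the circular battery on the
#' departure directions (Rayleigh, mean/rho, Watson two-sample; all
#' birds and first-night subsets) and the correlations of direction
#' with scaled stores (circular-linear) and with wind direction
#' (circular-circular). Models whose energy-store term would mix birds
#' measured at different times are restricted to first-night departers,
#' because stores change over a stopover. Subsets below the minimal n
#' of a procedure are skipped with a logged reason.
#'
#' @param birds bird table (see [read_bird_table()]; a synthetic one
#'   from [simulate_cohort()] works directly).
#' @param lat,lon stopover-site coordinates (used only when timing
#'   columns need recomputing; defaults are Helgoland).
#' @param circ_reps randomization replicates for correlation p-values.
#' @param seed integer seed for the randomization tests.
#' @param reference_species species treated as the model reference
#'   level (intercept); the other species enters as an indicator.
#' @return List of class \code{"study_report"}.
#' @export
run_study <- function(birds, lat = 54.1833, lon = 7.8833,
                      circ_reps = 10000, seed = 1,
                      reference_species = "CR") {
  skipped <- character(0)
  note <- function(msg) skipped <<- c(skipped, msg)

  b <- birds
  if ("dep.realtive.night" %in% names(b) && !"dep.relative.night" %in% names(b))
    names(b)[names(b) == "dep.realtive.night"] <- "dep.relative.night"
  b <- b[!is.na(b$days.on.island), , drop = FALSE]
  if (nrow(b) == 0) {
    return(structure(list(n = c(), skipped = "no birds with ascertained departures",
                          tests = list()), class = "study_report"))
  }
  b$Species <- factor(b$Species,
                      levels = c(reference_species,
                                 setdiff(unique(b$Species), reference_species)))
  b$lean <- lean_body_mass(as.character(b$Species), b$Muscle, b$Wing)
  b$stores <- energy_stores(b$Bodymass, b$lean)
  b$stores_scaled <- scale_within_species(b$stores, as.character(b$Species))
  b$first_night <- b$days.on.island == 1

  tests <- list()
  n_sp <- table(b$Species)
  sp2 <- levels(b$Species)[2] # the non-reference species, if any
  two_species <- !is.na(sp2) && all(n_sp >= 2)

  # -- energy stores: species comparison, capture-time effect ----------------
  if (two_species) {
    tests$lm_stores_species <- fit_linear_model(stores ~ Species, b)
  } else note("stores-by-species LM: need two species")
  cap <- .get_col(b, "Time")
  if (!is.null(cap)) {
    hr <- as.POSIXct(cap, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    b$capture_hour <- as.numeric(format(hr, "%H")) +
      as.numeric(format(hr, "%M")) / 60
    tests$lm_stores_capture <- lapply(stats::setNames(nm = levels(b$Species)),
      function(sp) {
        d <- b[b$Species == sp, ]
        if (nrow(d) < 3) { note(paste0("capture-time LM (", sp, "): n < 3")); return(NULL) }
        fit_linear_model(stores ~ capture_hour, d)
      })
  }

  # -- night-to-night decision ----------------------------------------------
  if (two_species) {
    tests$mw_stopover <- mann_whitney(b$days.on.island[b$Species == reference_species],
                                      b$days.on.island[b$Species == sp2])
    tab <- rbind(c(sum(b$first_night & b$Species == reference_species),
                   sum(!b$first_night & b$Species == reference_species)),
                 c(sum(b$first_night & b$Species == sp2),
                   sum(!b$first_night & b$Species == sp2)))
    tests$departure_fractions <- list(
      table = tab,
      fraction = stats::setNames(tab[, 1] / rowSums(tab), levels(b$Species)),
      fisher_p = fisher_exact_2x2(tab))
  } else note("stopover Mann-Whitney / Fisher: need two species")
  tests$mw_first_night_stores <- lapply(stats::setNames(nm = levels(b$Species)),
    function(sp) {
      d <- b[b$Species == sp, ]
      if (!any(d$first_night) || !any(!d$first_night)) {
        note(paste0("departer-vs-stayer stores MW (", sp,
                    "): one group empty")); return(NULL)
      }
      mann_whitney(d$stores[d$first_night], d$stores[!d$first_night])
    })

  # -- within-night decision -------------------------------------------------
  prop <- .get_col(b, "dep.relative.night")
  mins <- .get_col(b, "dep.min.sunset")
  fn <- b[b$first_night, , drop = FALSE]
  if (!is.null(prop)) {
    ok <- !is.na(prop) & prop > 0 & prop < 1
    if (two_species && sum(ok) > 3) {
      tests$beta_all <- beta_reg(dep.relative.night ~ Species, b[ok, ])
    } else note("beta regression (all birds): too few interior proportions")
    okf <- ok & b$first_night
    if (two_species && sum(okf) > 4) {
      tests$beta_first_night <- beta_reg(
        dep.relative.night ~ Species + stores_scaled, b[okf, ])
    } else note("beta regression (first night): too few interior proportions")
  } else note("beta regressions: no proportion-of-night column")
  if (!is.null(mins)) {
    if (two_species && sum(!is.na(mins)) > 3) {
      tests$lm_timing_all <- fit_linear_model(dep.min.sunset ~ Species,
                                              b[!is.na(mins), ],
                                              log10_response = TRUE)
    }
    if (two_species && sum(!is.na(fn$dep.min.sunset)) > 4) {
      tests$lm_timing_first_night <- fit_linear_model(
        dep.min.sunset ~ Species + stores_scaled,
        fn[!is.na(fn$dep.min.sunset), ], log10_response = TRUE)
    } else note("timing LM (first night): too few birds")
    cr1 <- fn[fn$Species == reference_species & !is.na(fn$dep.min.sunset), ]
    if (nrow(cr1) >= 4) {
      tests$lm_minutes_stores_ref_species <- fit_linear_model(
        dep.min.sunset ~ stores_scaled, cr1)
    } else note("reference-species minutes-vs-stores LM: n < 4")
  } else note("timing LMs: no minutes-after-sunset column")

  # -- directional decision --------------------------------------------------
  dir_col <- .get_col(b, "dep.dir")
  if (!is.null(dir_col)) {
    b$dep.dir <- dir_col
    circ_group <- function(d, label) {
      th <- d$dep.dir[!is.na(d$dep.dir)]
      if (length(th) < 2) { note(paste0("Rayleigh (", label, "): n < 2")); return(NULL) }
      rt <- rayleigh_test(th)
      cm <- circ_mean_rho(th)
      list(n = rt$n, rho = rt$rho, p = rt$p,
           mean = cm$mean, mean_reported = rt$p < 0.05)
    }
    grp <- list()
    for (sp in levels(b$Species)) {
      grp[[paste0(sp, "_all")]] <- circ_group(b[b$Species == sp, ], paste0(sp, " all"))
      grp[[paste0(sp, "_first_night")]] <-
        circ_group(fn[fn$Species == sp, ], paste0(sp, " first night"))
    }
    tests$directions <- grp
    wats <- function(d1, d2, label) {
      a <- d1$dep.dir[!is.na(d1$dep.dir)]
      bb <- d2$dep.dir[!is.na(d2$dep.dir)]
      if (length(a) < 4 || length(bb) < 4) {
        note(paste0("Watson (", label, "): n < 4")); return(NULL)
      }
      watson_two_sample(a, bb)
    }
    if (two_species) {
      tests$watson_all <- wats(b[b$Species == reference_species, ],
                               b[b$Species == sp2, ], "all birds")
      tests$watson_first_night <- wats(fn[fn$Species == reference_species, ],
                                       fn[fn$Species == sp2, ], "first night")
    }
    tests$circ_lin_stores <- lapply(stats::setNames(nm = levels(b$Species)),
      function(sp) {
        d <- fn[fn$Species == sp & !is.na(fn$dep.dir), ]
        if (nrow(d) < 4) {
          note(paste0("stores-vs-direction correlation (", sp, "): n < 4"))
          return(NULL)
        }
        circ_lin_cor(d$dep.dir, d$stores_scaled, reps = circ_reps, seed = seed)
      })
    wind <- .get_col(b, "wind.dir")
    if (!is.null(wind)) {
      tests$circ_circ_wind <- lapply(stats::setNames(nm = levels(b$Species)),
        function(sp) {
          sel <- b$Species == sp & !is.na(b$dep.dir) & !is.na(wind)
          d <- b[sel, , drop = FALSE]
          w <- wind[sel]
          if (nrow(d) < 4 || stats::sd(w) == 0) {
            note(paste0("wind-vs-direction correlation (", sp,
                        "): n < 4 or constant wind"))
            return(NULL)
          }
          circ_circ_cor(d$dep.dir, w, reps = circ_reps, seed = seed)
        })
    }
  } else note("directional analyses: no bearing column")

  structure(list(
    n = as.list(n_sp),
    n_first_night = as.list(table(b$Species[b$first_night])),
    birds = b, tests = tests, skipped = skipped
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Stopover departure study report\n")
  cat("Birds analysed:", paste(names(x$n), unlist(x$n), sep = "=", collapse = ", "),
      "; first-night departers:",
      paste(names(x$n_first_night), unlist(x$n_first_night), sep = "=",
            collapse = ", "), "\n\n")
  t <- x$tests
  if (!is.null(t$lm_stores_species)) {
    cat("-- Energy stores by species (LM) --\n"); print(t$lm_stores_species)
  }
  if (!is.null(t$mw_stopover))
    cat("\nMinimum stopover, Mann-Whitney: W =", t$mw_stopover$W,
        ", p =", format(t$mw_stopover$p, digits = 3), "\n")
  if (!is.null(t$departure_fractions)) {
    f <- t$departure_fractions
    cat("First-night departure fractions:",
        paste(names(f$fraction), sprintf("%.0f%%", 100 * f$fraction),
              collapse = ", "),
        "; Fisher p =", format(f$fisher_p, digits = 3), "\n")
  }
  for (sp in names(t$mw_first_night_stores)) {
    m <- t$mw_first_night_stores[[sp]]
    if (!is.null(m))
      cat("Stores, departers vs stayers (", sp, "), Mann-Whitney: W =", m$W,
          ", p =", format(m$p, digits = 3), "\n")
  }
  if (!is.null(t$beta_all)) {
    cat("\n-- Beta regression, proportion of night, all birds --\n")
    print(summary(t$beta_all))
  }
  if (!is.null(t$beta_first_night)) {
    cat("\n-- Beta regression, proportion of night, first night --\n")
    print(summary(t$beta_first_night))
  }
  if (!is.null(t$lm_timing_all)) {
    cat("\n-- log10 minutes after sunset ~ species, all birds --\n")
    print(t$lm_timing_all)
  }
  if (!is.null(t$lm_timing_first_night)) {
    cat("\n-- log10 minutes after sunset ~ species + stores, first night --\n")
    print(t$lm_timing_first_night)
  }
  if (!is.null(t$lm_minutes_stores_ref_species)) {
    cat("\n-- minutes after sunset ~ scaled stores, reference species, first night --\n")
    print(t$lm_minutes_stores_ref_species)
  }
  if (!is.null(t$directions)) {
    cat("\n-- Departure directions --\n")
    for (nm in names(t$directions)) {
      g <- t$directions[[nm]]
      if (is.null(g)) next
      cat(sprintf("%-18s rho = %.2f, n = %d, Rayleigh p = %.4g%s\n", nm,
                  g$rho, g$n, g$p,
                  if (g$mean_reported) sprintf(", mean = %.0f deg", g$mean)
                  else " (mean not reported; uniformity not rejected)"))
    }
    wprint <- function(w, lab) if (!is.null(w))
      cat(sprintf("Watson two-sample (%s): U2 = %.3f, %s\n", lab, w$u2,
                  if (w$p_lo == 0) paste("p <", w$p_hi)
                  else paste0(w$p_lo, " < p <= ", w$p_hi)))
    wprint(x$tests$watson_all, "all birds")
    wprint(x$tests$watson_first_night, "first night")
  }
  if (length(x$skipped)) {
    cat("\nSkipped analyses:\n")
    for (s in x$skipped) cat(" -", s, "\n")
  }
  invisible(x)
}

#' Export a study report as JSON
#'
#' Serialises the numerical content of a [run_study()] report (every
#' statistic with its n; model objects reduced to coefficient tables)
#' to a machine-readable JSON file.
#'
#' @param report a \code{"study_report"}.
#' @param file output path; when NULL the JSON string is returned.
#' @export
report_json <- function(report, file = NULL) {
  shrink <- function(x) {
    if (inherits(x, "beta_reg")) {
      return(list(coefficients = as.list(x$coefficients),
                  se = as.list(x$se), z = as.list(x$z), p = as.list(x$p),
                  phi = x$phi, pseudo_r2 = x$pseudo_r2, n = x$n))
    }
    if (inherits(x, "linear_fit")) {
      cf <- x$coefficients
      return(list(coefficients = as.list(cf[, 1]), se = as.list(cf[, 2]),
                  t = as.list(cf[, 3]), p = as.list(cf[, 4]),
                  r_squared = x$r_squared, f = x$f, df = x$df, n = x$n))
    }
    if (is.list(x)) return(lapply(x, shrink))
    x
  }
  out <- list(n = report$n, n_first_night = report$n_first_night,
              tests = shrink(report$tests), skipped = report$skipped)
  if (is.null(file)) {
    jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA, null = "null")
  }
}
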