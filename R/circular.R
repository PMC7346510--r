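# Circular descriptive and inferential statistics for departure bearings.
# Angles are degrees in [0, 360) at the interface and radians internally.

.circ_rad <- function(deg) deg * pi / 180

#' Weighted circular mean and mean resultant length
#'
#' The mean direction is the angle of the (weighted) mean unit vector,
#' \eqn{atan2(\sum w \sin\theta, \sum w \cos\theta)}; the mean resultant
#' length \eqn{\rho = |\sum w e^{i\theta}| / \sum w} measures
#' concentration (1 = all angles identical, 0 = balanced dispersion).
#' When the resultant vanishes the mean direction is undefined and
#' returned as \code{NA}.
#'
#' @param theta numeric vector of angles in degrees.
#' @param w optional non-negative weights (default equal).
#' @return List with \code{mean} (degrees in [0, 360), or NA) and
#'   \code{rho} (in [0, 1]).
#' @export
circ_mean_rho <- function(theta, w = NULL) {
  if (length(theta) < 1) stop("need at least one angle")
  if (is.null(w)) w <- rep(1, length(theta))
  if (length(w) != length(theta)) stop("weights must match angles in length")
  if (any(w < 0) || all(w == 0)) stop("weights must be non-negative, not all zero")
  th <- .circ_rad(theta)
  S <- sum(w * sin(th))
  C <- sum(w * cos(th))
  rho <- sqrt(S^2 + C^2) / sum(w)
  mean_dir <- if (sqrt(S^2 + C^2) < 1e-12) NA_real_ else (atan2(S, C) * 180 / pi) %% 360
  list(mean = mean_dir, rho = rho)
}

#' Rayleigh test p-value from the mean resultant length
#'
#' The refined Rayleigh approximation used by standard circular-statistics
#' software: with \eqn{R = n\rho},
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n))}.
#' Exposed separately from [rayleigh_test()] so that published
#' \eqn{(\rho, n)} pairs can be checked without the raw angles.
#'
#' @param rho mean resultant length in [0, 1].
#' @param n sample size (>= 2).
#' @return The p-value (clamped to [0, 1]; never exactly zero for finite
#'   \code{n}).
#' @export
rayleigh_p <- function(rho, n) {
  if (n < 2) stop("Rayleigh test needs n >= 2")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  R <- n * rho
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  min(max(p, .Machine$double.xmin), 1)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that a circular sample is uniformly
#' distributed; a small p indicates directedness. Significance is
#' conventionally required before a mean direction is reported.
#'
#' @param theta numeric vector of angles in degrees (n >= 2).
#' @return List with \code{rho}, \code{n} and \code{p}.
#' @export
rayleigh_test <- function(theta) {
  n <- length(theta)
  if (n < 2) stop("Rayleigh test needs n >= 2")
  rho <- circ_mean_rho(theta)$rho
  list(rho = rho, n = n, p = rayleigh_p(rho, n))
}

# critical values of Watson's two-sample U2 (large-sample table)
.watson_u2_table <- data.frame(
  crit = c(0.385, 0.268, 0.187, 0.152),
  p    = c(0.001, 0.01, 0.05, 0.1)
)

#' Watson's two-sample U-squared test
#'
#' Non-parametric test that two circular samples come from a common
#' distribution, based on the squared deviations between the two
#' empirical cumulative distributions around the circle. The p-value is
#' reported as a bracket from the standard critical-value table
#' (\code{p_lo < p <= p_hi}); a seeded permutation p-value can be added
#' with \code{perm_reps}.
#'
#' @param a,b numeric vectors of angles in degrees, each with n >= 4.
#' @param perm_reps if > 0, number of label permutations used to compute
#'   an additional Monte-Carlo p-value.
#' @param seed optional integer seed for the permutation p-value.
#' @return List with \code{u2} (the statistic), \code{p_lo}, \code{p_hi}
#'   (table bracket, 0 and 1 at the extremes) and, when requested,
#'   \code{p_perm}.
#' @export
watson_two_sample <- function(a, b, perm_reps = 0, seed = NULL) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 4 || n2 < 4) stop("Watson two-sample test needs n >= 4 per sample")
  u2 <- .watson_u2_stat(a, b)
  i <- which(u2 > .watson_u2_table$crit)
  if (length(i)) {
    p_lo <- 0
    p_hi <- .watson_u2_table$p[min(i)]
    if (min(i) > 1) p_lo <- .watson_u2_table$p[min(i) - 1]
  } else {
    p_lo <- 0.1; p_hi <- 1
  }
  out <- list(u2 = u2, p_lo = p_lo, p_hi = p_hi)
  if (perm_reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    pooled <- c(a, b)
    exceed <- 0L
    for (r in seq_len(perm_reps)) {
      idx <- sample.int(n1 + n2, n1)
      if (.watson_u2_stat(pooled[idx], pooled[-idx]) >= u2) exceed <- exceed + 1L
    }
    out$p_perm <- (exceed + 1) / (perm_reps + 1)
  }
  out
}

# U2 from the pooled circular order; ties are processed as one block
# (mid-position), with a warning when present
.watson_u2_stat <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  x <- c(a, b) %% 360
  g <- rep(1:2, c(n1, n2))
  o <- order(x)
  x <- x[o]; g <- g[o]
  if (anyDuplicated(x)) warning("ties between the two circular samples; using mid-positions")
  d <- numeric(N)
  cum1 <- 0; cum2 <- 0
  k <- 1; pos <- 1
  while (k <= N) {
    tie <- which(x == x[k])
    tie <- tie[tie >= k]
    cum1 <- cum1 + sum(g[tie] == 1)
    cum2 <- cum2 + sum(g[tie] == 2)
    d[pos:(pos + length(tie) - 1)] <- cum1 / n1 - cum2 / n2
    pos <- pos + length(tie)
    k <- k + length(tie)
  }
  (n1 * n2) / N^2 * (sum(d^2) - sum(d)^2 / N)
}

#' Circular-linear correlation with a randomization p-value
#'
#' The circular-linear correlation of an angle \eqn{\theta} with a linear
#' variable \eqn{x} is built from the three Pearson correlations
#' \eqn{r_{xc} = cor(x, \cos\theta)}, \eqn{r_{xs} = cor(x, \sin\theta)}
#' and \eqn{r_{cs} = cor(\cos\theta, \sin\theta)}:
#' \deqn{r^2 = (r_{xc}^2 + r_{xs}^2 - 2 r_{xc} r_{xs} r_{cs}) / (1 - r_{cs}^2).}
#' The p-value is a randomization estimate: each replicate draws, with
#' replacement and independently, a resample of the angles and a
#' resample of the linear values (breaking any pairing, which is the
#' null of no association), and p is the fraction of replicates whose
#' correlation exceeds the observed one.
#'
#' @param theta numeric vector of angles in degrees.
#' @param x numeric vector, same length, with non-zero variance.
#' @param reps number of randomization replicates.
#' @param seed optional integer seed making the p-value reproducible.
#' @return List with \code{r} (in [0, 1]), \code{p} and \code{reps}.
#' @export
circ_lin_cor <- function(theta, x, reps = 10000, seed = NULL) {
  n <- length(theta)
  if (length(x) != n) stop("theta and x must have the same length")
  if (n < 4) stop("need n >= 4")
  if (stats::sd(x) == 0) stop("x has zero variance")
  r_obs <- .circ_lin_r(.circ_rad(theta), x)
  if (!is.null(seed)) set.seed(seed)
  th <- .circ_rad(theta)
  exceed <- 0L
  for (i in seq_len(reps)) {
    r_star <- .circ_lin_r(th[sample.int(n, n, replace = TRUE)],
                          x[sample.int(n, n, replace = TRUE)])
    if (!is.na(r_star) && r_star > r_obs) exceed <- exceed + 1L
  }
  list(r = r_obs, p = exceed / reps, reps = reps)
}

#' Circular-circular correlation with a randomization p-value
#'
#' The Jammalamadaka-SenGupta circular correlation coefficient between
#' two angles,
#' \deqn{r = \frac{\sum \sin(\alpha_i - \bar\alpha)\sin(\beta_i - \bar\beta)}
#'   {\sqrt{\sum \sin^2(\alpha_i - \bar\alpha)\sum \sin^2(\beta_i - \bar\beta)}},}
#' with \eqn{\bar\alpha, \bar\beta} the sample mean directions. Used for
#' wind direction versus departure direction. The p-value is estimated
#' by the same independent with-replacement randomization scheme as
#' [circ_lin_cor()], two-sided on |r|.
#'
#' @param alpha,beta numeric vectors of angles in degrees, equal length
#'   (n >= 4).
#' @param reps number of randomization replicates.
#' @param seed optional integer seed.
#' @return List with \code{r} (in [-1, 1]), \code{p} and \code{reps}.
#' @export
circ_circ_cor <- function(alpha, beta, reps = 10000, seed = NULL) {
  n <- length(alpha)
  if (length(beta) != n) stop("alpha and beta must have the same length")
  if (n < 4) stop("need n >= 4")
  a <- .circ_rad(alpha); b <- .circ_rad(beta)
  r_obs <- .circ_circ_r(a, b)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (i in seq_len(reps)) {
    r_star <- .circ_circ_r(a[sample.int(n, n, replace = TRUE)],
                           b[sample.int(n, n, replace = TRUE)])
    if (!is.na(r_star) && abs(r_star) > abs(r_obs)) exceed <- exceed + 1L
  }
  list(r = r_obs, p = exceed / reps, reps = reps)
}

.circ_circ_r <- function(a, b) {
  ma <- atan2(sum(sin(a)), sum(cos(a)))
  mb <- atan2(sum(sin(b)), sum(cos(b)))
  sa <- sin(a - ma); sb <- sin(b - mb)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den == 0) return(NA_real_)
  sum(sa * sb) / den
}

.circ_lin_r <- function(th, x) {
  cs <- cos(th); sn <- sin(th)
  if (stats::sd(cs) == 0 || stats::sd(sn) == 0 || stats::sd(x) == 0) return(NA_real_)
  rxc <- stats::cor(x, cs); rxs <- stats::cor(x, sn); rcs <- stats::cor(cs, sn)
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  sqrt(max(0, min(1, r2)))
}
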