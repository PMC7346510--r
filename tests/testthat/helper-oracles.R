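# Independent brute-force oracles used across the suite. These are written
# naively on purpose: they must not share code with the implementation.

# weighted circular mean by explicit vector summation
brute_weighted_circ_mean <- function(bearings, weights) {
  vx <- 0; vy <- 0
  for (i in seq_along(bearings)) {
    vx <- vx + weights[i] * sin(bearings[i] * pi / 180)
    vy <- vy + weights[i] * cos(bearings[i] * pi / 180)
  }
  (atan2(vx, vy) * 180 / pi) %% 360
}

# Mann-Whitney U for sample a: count of pairs a_i > b_j plus half the ties
brute_mw_U <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    if (ai > bj) u <- u + 1
    else if (ai == bj) u <- u + 0.5
  }
  u
}

# two-sided Fisher exact p by enumerating all tables with the observed margins
brute_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  p <- 0
  for (k in max(0, r1 - (n - c1)):min(r1, c1)) {
    pk <- stats::dhyper(k, c1, n - c1, r1)
    if (pk <= p_obs * (1 + 1e-7)) p <- p + pk
  }
  p
}

# circular-linear correlation straight from its defining Pearson correlations
brute_circ_lin_r <- function(theta_deg, x) {
  th <- theta_deg * pi / 180
  rxc <- stats::cor(x, cos(th)); rxs <- stats::cor(x, sin(th))
  rcs <- stats::cor(cos(th), sin(th))
  sqrt((rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2))
}

# beta-regression log-likelihood evaluated directly from dbeta
beta_loglik_at <- function(y, X, beta, phi) {
  mu <- stats::plogis(drop(X %*% beta))
  sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

# wrapped-normal angles: enough von Mises realism for separation tests
rwrapped <- function(n, mean_deg, sd_deg) (stats::rnorm(n, mean_deg, sd_deg)) %% 360

# a minimal hand-built departure stream: stationary baseline, surge, decay
make_departure_stream <- function(t0, baseline = 45, peak = 70,
                                  pre_min = 30, decay_min = 20,
                                  interval = 10, antenna = "A000",
                                  tag = "T1") {
  pre_t <- seq(t0 - pre_min * 60, t0 - interval, by = interval)
  dec_t <- seq(t0, t0 + decay_min * 60, by = interval)
  sig <- c(rep(baseline, length(pre_t)),
           peak - (dec_t - t0) / (decay_min * 60) * (peak - baseline + 15))
  data.frame(time = as.POSIXct(c(pre_t, dec_t), origin = "1970-01-01", tz = "UTC"),
             tag_id = tag, antenna_id = antenna, signal = sig,
             stringsAsFactors = FALSE)
}
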