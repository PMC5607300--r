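# Shared fixtures: tiny calibration curves built in code.

# Identity curve: mu(t) = t with constant curve error.
identity_curve <- function(span = c(0, 12000), sigma = 0) {
  cal_curve(span, span, rep(sigma, 2), name = "identity")
}

# Piecewise-linear curve with a radiocarbon plateau: mu is constant over
# [plateau_from, plateau_to] cal BP and linear (slope 1) elsewhere.
plateau_curve <- function(span = c(4000, 9000), plateau = c(6000, 6300),
                          sigma = 20) {
  knots <- sort(unique(c(span, plateau)))
  mu <- ifelse(knots <= plateau[1], knots,
               ifelse(knots <= plateau[2], plateau[1],
                      knots - (plateau[2] - plateau[1])))
  cal_curve(knots, mu, rep(sigma, length(knots)), name = "plateau")
}

# Brute-force calibration oracle: per-cell Gaussian evaluation and
# renormalisation over the full curve grid, no truncation. Kept naive and
# independent of calibrate().
oracle_calibrate <- function(cra, error, curve) {
  w <- numeric(length(curve$grid))
  for (i in seq_along(curve$grid)) {
    s <- sqrt(error^2 + curve$sigma[i]^2)
    w[i] <- exp(-0.5 * ((cra - curve$mu[i]) / s)^2) / s
  }
  w / sum(w)
}

# A minimal date table with singleton sites.
singleton_dates <- function(cra, error, period = "Neolithic") {
  n <- length(cra)
  data.frame(lab_code = sprintf("X-%d", seq_len(n)), cra = cra,
             error = rep_len(error, n),
             site = sprintf("site%d", seq_len(n)),
             lon = rep(10, n), lat = rep(45, n),
             period = rep_len(period, n), culture = NA_character_)
}
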