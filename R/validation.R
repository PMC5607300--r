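# Self-calibration experiments for the Monte-Carlo SPD test. These are
# the package's own operating-characteristic checks: the rank-based
# global p-value should reject a true null about 5% of the time at
# alpha = 0.05, and the pointwise 95% envelope should contain a held-out
# null SPD at about 95% of grid points.

# One null data set: n singleton-bin dates drawn from the exponential
# model over the window, pushed through the curve and recalibrated.
simulate_null_spd <- function(n, rate, curve, window, error_range) {
  ages <- draw_exponential_ages(n, rate, min(window), max(window))
  g0 <- curve$grid[1L]; ng <- length(curve$grid)
  pos <- ages - g0 + 1
  i0 <- pmin(pmax(floor(pos), 1L), ng - 1L)
  fr <- pos - i0
  mu_t <- curve$mu[i0] * (1 - fr) + curve$mu[i0 + 1L] * fr
  sc_t <- curve$sigma[i0] * (1 - fr) + curve$sigma[i0 + 1L] * fr
  err <- stats::runif(n, error_range[1L], error_range[2L])
  cra <- mu_t + stats::rnorm(n, 0, sqrt(sc_t^2 + err^2))
  grid <- seq(min(window), max(window))
  w0 <- grid[1L] - g0 + 1L
  w1 <- grid[length(grid)] - g0 + 1L
  dens <- .spd_sum_c(cra, err, curve$mu, curve$sigma, w0, w1)
  list(spd = structure(list(grid = grid, density = dens, n_bins = n,
                            scale = "raw",
                            window = c(max(window), min(window)),
                            corrected = FALSE, bin_densities = NULL),
                       class = "spd"),
       errors = err)
}

#' False-positive calibration of the Monte-Carlo SPD test
#'
#' Repeatedly simulates date sets from a fixed exponential null, runs the
#' full test on each (exponential fit to the observed SPD, seeded
#' simulation ensemble, global p-value) and reports the rejection rate at
#' `alpha`. With a well-calibrated test the rate is close to `alpha`:
#' about 5% of true nulls appear significant.
#'
#' @param n_rep number of replicate data sets (default 200).
#' @param n_sim ensemble size per test (default 500).
#' @param n_bins dates (singleton site-phase bins) per data set.
#' @param rate annual growth rate of the generating null (fraction/yr).
#' @param curve a monotone [cal_curve]; default [toy_curve()].
#' @param window c(oldest, youngest) cal BP test window.
#' @param error_range laboratory errors drawn uniformly from this range.
#' @param alpha significance level (default 0.05).
#' @param seed integer; replicate i draws data under `seed + i` and its
#'   ensemble under `seed + 100000 + i`.
#' @return list with `p` (vector of global p-values), `fp_rate`
#'   (fraction below `alpha`) and `fp_pct` (the same in percent).
#' @export
mcspd_null_calibration <- function(n_rep = 200L, n_sim = 500L,
                                   n_bins = 100L, rate = 3e-4,
                                   curve = toy_curve(),
                                   window = c(10000, 6000),
                                   error_range = c(20, 120),
                                   alpha = 0.05, seed) {
  if (missing(seed)) stop("mcspd_null_calibration requires a seed")
  p <- vapply(seq_len(n_rep), function(i) {
    set.seed(seed + i)
    obs <- simulate_null_spd(n_bins, rate, curve, window, error_range)
    fit <- fit_exponential(obs$spd, n_boot = 0)
    ens <- simulate_ensemble(fit, n_bins = n_bins,
                             error_pool = obs$errors, curve = curve,
                             window = window, n_sim = n_sim,
                             seed = seed + 100000L + i)
    global_pvalue(obs$spd, ens)$p
  }, 0.0)
  list(p = p, fp_rate = mean(p < alpha), fp_pct = 100 * mean(p < alpha))
}

#' Empirical coverage of the pointwise 95% simulation envelope
#'
#' Builds the envelope from one null ensemble, then measures, over
#' held-out null SPDs, the average fraction of calendar grid points at
#' which the held-out curve lies inside the band. The construction
#' targets 95% pointwise coverage (2.5% exceedance per side).
#'
#' @param n_sim ensemble size used to build the envelope (default 500).
#' @param n_held held-out null curves (default 200).
#' @param n_bins dates per simulated SPD.
#' @param rate annual growth rate of the null (fraction/yr).
#' @param curve a monotone [cal_curve].
#' @param window c(oldest, youngest) cal BP.
#' @param error_range laboratory errors drawn uniformly from this range.
#' @param seed integer seed.
#' @return list with `coverage` (per held-out curve), `mean_coverage` and
#'   `mean_coverage_pct`.
#' @export
envelope_coverage <- function(n_sim = 500L, n_held = 200L, n_bins = 100L,
                              rate = 3e-4, curve = toy_curve(),
                              window = c(10000, 6000),
                              error_range = c(20, 120), seed) {
  if (missing(seed)) stop("envelope_coverage requires a seed")
  set.seed(seed)
  ref <- simulate_null_spd(n_bins, rate, curve, window, error_range)
  fit <- fit_exponential(ref$spd, n_boot = 0)
  ens <- simulate_ensemble(fit, n_bins = n_bins, error_pool = ref$errors,
                           curve = curve, window = window, n_sim = n_sim,
                           seed = seed + 1L)
  env <- mc_envelope(ref$spd, ens)
  tot <- sum(ref$spd$density)
  cover <- vapply(seq_len(n_held), function(i) {
    set.seed(seed + 200000L + i)
    held <- simulate_null_spd(n_bins, rate, curve, window, error_range)
    d <- held$spd$density * tot / sum(held$spd$density)  # mass matching
    mean(d >= env$lo & d <= env$hi)
  }, 0.0)
  list(coverage = cover, mean_coverage = mean(cover),
       mean_coverage_pct = 100 * mean(cover))
}
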