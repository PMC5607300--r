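#' Fit a Mesolithic-only exponential null model for a region
#'
#' The demographic null for a region is the exponential trend of its
#' forager (Mesolithic) record up to the local arrival of farming: only
#' dates labelled Mesolithic, within `[window_old, neolithization]`, enter
#' the site-phase binning, SPD and fit. Neolithic dates in the region have
#' no influence on the null.
#'
#' @param dates regional date table (`site`, `cra`, `error`, `period`).
#' @param curve a [cal_curve].
#' @param neolithization cal BP of local farming arrival (young end of the
#'   null window).
#' @param window_old old end of the null window (default 12000 cal BP).
#' @param h site-phase binning width (14C yr).
#' @param min_bins minimum number of Mesolithic bins required (default 10).
#' @return Object of class `null_model`: list with `fit` (a `growth_fit`),
#'   `window`, `n_bins`, `spd`.
#' @export
fit_null <- function(dates, curve, neolithization, window_old = 12000,
                     h = 200, min_bins = 10L) {
  stopifnot("period" %in% names(dates))
  meso <- dates[dates$period == "Mesolithic", , drop = FALSE]
  if (!nrow(meso))
    stop(insufficient_data_error(0L, "no Mesolithic dates in region"))
  binned <- bin_dates(meso, h = h)
  nb <- attr(binned, "n_bins")
  if (nb < min_bins)
    stop(insufficient_data_error(
      nb, sprintf("only %d Mesolithic bins (< %d)", nb, min_bins)))
  s <- compute_spd(binned, curve, window = c(window_old, neolithization))
  fit <- fit_exponential(s, n_boot = 0)
  structure(list(fit = fit, window = c(window_old, neolithization),
                 n_bins = nb, spd = s),
            class = "null_model")
}

insufficient_data_error <- function(n_bins, msg) {
  structure(class = c("insufficient_data", "error", "condition"),
            list(message = msg, call = sys.call(-1), n_bins = n_bins))
}

#' Simulate an SPD ensemble under an exponential null model
#'
#' Each simulation draws `n_bins` calendar ages from the exponential null
#' over the test window, converts each to a synthetic radiocarbon
#' measurement through the curve (laboratory errors resampled with
#' replacement from the observed pool; the curve error enters in this
#' single draw), recalibrates, and sums the dates as singleton bins. The
#' whole ensemble is reproducible from `seed`.
#'
#' @param model a `null_model` (or a bare `growth_fit`).
#' @param n_bins number of dates per simulation, normally the observed
#'   site-phase count.
#' @param error_pool observed laboratory errors to resample from.
#' @param curve a [cal_curve] with non-decreasing mu (simulation requires
#'   the curve to be invertible).
#' @param window c(oldest, youngest) cal BP test window.
#' @param n_sim ensemble size (default 1000).
#' @param seed integer seed (required: ensembles must be reproducible).
#' @return Object of class `spd_ensemble`: list with `grid`, `sims` (matrix
#'   grid x n_sim), `rate`, `n_bins`, `n_sim`, `seed`.
#' @export
simulate_ensemble <- function(model, n_bins, error_pool, curve, window,
                              n_sim = 1000L, seed) {
  fit <- if (inherits(model, "null_model")) model$fit else model
  stopifnot(inherits(fit, "growth_fit"), length(error_pool) >= 1L)
  if (missing(seed)) stop("simulate_ensemble requires an explicit seed")
  if (is.unsorted(curve$mu))
    stop("simulation requires a curve with non-decreasing mu")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  grid <- seq(min(window), max(window))
  w0 <- grid[1L] - curve$grid[1L] + 1L
  w1 <- grid[length(grid)] - curve$grid[1L] + 1L
  if (w0 < 1L || w1 > length(curve$grid))
    stop("test window outside calibration curve span")
  sims <- matrix(0, nrow = length(grid), ncol = n_sim)
  g0 <- curve$grid[1L]; ng <- length(curve$grid)
  for (j in seq_len(n_sim)) {
    ages <- draw_exponential_ages(n_bins, fit$rate, min(window), max(window))
    # linear interpolation on the 1-yr curve grid, done by index
    pos <- ages - g0 + 1
    i0 <- pmin(pmax(floor(pos), 1L), ng - 1L)
    fr <- pos - i0
    mu_t <- curve$mu[i0] * (1 - fr) + curve$mu[i0 + 1L] * fr
    sc_t <- curve$sigma[i0] * (1 - fr) + curve$sigma[i0 + 1L] * fr
    err <- sample(error_pool, n_bins, replace = TRUE)
    cra <- mu_t + stats::rnorm(n_bins, 0, sqrt(sc_t^2 + err^2))
    sims[, j] <- .spd_sum_c(cra, err, curve$mu, curve$sigma, w0, w1)
  }
  structure(list(grid = grid, sims = sims, rate = fit$rate,
                 n_bins = n_bins, n_sim = n_sim, seed = seed),
            class = "spd_ensemble")
}

# Inverse-CDF draw from density proportional to exp(-r * t) on [t1, t2]
# (t in cal BP; r > 0 concentrates mass toward the present).
draw_exponential_ages <- function(n, r, t1, t2) {
  u <- stats::runif(n)
  if (abs(r) < 1e-12) return(t1 + u * (t2 - t1))
  e1 <- exp(-r * t1); e2 <- exp(-r * t2)
  -log(e1 - u * (e1 - e2)) / r
}

#' Simulation envelope and significance regions
#'
#' Matches each simulated SPD to the observed total mass, takes pointwise
#' 2.5% and 97.5% quantiles as the 95% envelope, and records contiguous
#' calendar intervals where the observed SPD escapes the envelope, with
#' direction.
#'
#' @param observed an `spd` on the ensemble grid.
#' @param ensemble an `spd_ensemble`.
#' @return list with `grid`, `lo`, `hi` (envelope), `sig_regions`
#'   (data.frame: `start`, `end` cal BP, `direction` "above"/"below") and
#'   `matched_sims` (the mass-matched simulation matrix, reused by
#'   [global_pvalue()]).
#' @export
mc_envelope <- function(observed, ensemble) {
  stopifnot(inherits(observed, "spd"), inherits(ensemble, "spd_ensemble"))
  if (!identical(as.integer(observed$grid), as.integer(ensemble$grid)))
    stop("observed SPD and ensemble are on different grids")
  tot <- sum(observed$density)
  cs <- colSums(ensemble$sims)
  f <- ifelse(cs > 0, tot / cs, 0)
  sims <- sweep(ensemble$sims, 2L, f, `*`)
  qs <- .row_quantiles_c(sims, 0.025, 0.975)
  lo <- qs[, 1L]; hi <- qs[, 2L]
  above <- observed$density > hi
  below <- observed$density < lo
  runs <- function(flag, dir) {
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    k <- which(r$values)
    if (!length(k)) return(NULL)
    data.frame(start = observed$grid[ends[k]],   # older boundary
               end = observed$grid[starts[k]],
               direction = dir)
  }
  sig <- rbind(runs(above, "above"), runs(below, "below"))
  if (is.null(sig))
    sig <- data.frame(start = numeric(0), end = numeric(0),
                      direction = character(0))
  list(grid = observed$grid, lo = lo, hi = hi,
       sig_regions = sig[order(-sig$start), , drop = FALSE],
       matched_sims = sims)
}

#' Global p-value of the Monte-Carlo SPD test
#'
#' Standardises the observed and each simulated SPD pointwise by the
#' ensemble mean and standard deviation; the test statistic is the total
#' standardised mass lying outside the pointwise 95% simulation band
#' (both tails). The p-value is the rank of the observed statistic in the
#' simulated statistics with the +1 correction, so it is never zero.
#' Grid points with zero ensemble variance carry no information and are
#' excluded from the statistic.
#'
#' @param observed an `spd` on the ensemble grid.
#' @param ensemble an `spd_ensemble`.
#' @param env optional result of [mc_envelope()] to avoid recomputation.
#' @return list with `p`, `stat_obs`, `stat_sims`, `n_excluded` (zero-
#'   variance grid points).
#' @export
global_pvalue <- function(observed, ensemble, env = NULL) {
  if (is.null(env)) env <- mc_envelope(observed, ensemble)
  sims <- env$matched_sims
  m <- rowMeans(sims)
  s <- sqrt(pmax(rowMeans(sims^2) - m^2, 0) * ncol(sims) / (ncol(sims) - 1L))
  ok <- s > 0
  n_excluded <- sum(!ok)
  excess <- function(x) {
    sum(pmax((x - env$hi)[ok] / s[ok], 0)) +
      sum(pmax((env$lo - x)[ok] / s[ok], 0))
  }
  stat_obs <- excess(observed$density)
  stat_sims <- colSums(pmax((sims - env$hi) / s, 0)[ok, , drop = FALSE]) +
    colSums(pmax((env$lo - sims) / s, 0)[ok, , drop = FALSE])
  p <- (1 + sum(stat_sims >= stat_obs)) / (ncol(sims) + 1)
  list(p = p, stat_obs = stat_obs, stat_sims = stat_sims,
       n_excluded = n_excluded)
}

#' Monte-Carlo SPD test of a regional date set
#'
#' End-to-end regional test: bins all dates and builds the observed SPD
#' over the test window; fits the Mesolithic-only exponential null up to
#' the Neolithization date; simulates the null ensemble with the observed
#' number of site-phase bins and laboratory-error pool; and returns the
#' 95% envelope, significance regions and global p-value.
#'
#' @param dates regional date table (`site`, `cra`, `error`, `period`).
#' @param curve a [cal_curve] (non-decreasing mu).
#' @param window c(oldest, youngest) cal BP test window.
#' @param neolithization cal BP of local farming arrival; defaults to the
#'   calibrated mode of the region's oldest Neolithic date.
#' @param h binning width (14C yr, default 200).
#' @param n_sim ensemble size (default 1000).
#' @param seed integer seed for the ensemble.
#' @return Object of class `mcspd_test`: list with `observed`, `null`,
#'   `ensemble` summary (`rate`, `n_sim`, `seed`), `envelope` (grid, lo,
#'   hi), `sig_regions`, `p`, `n_bins`, `neolithization`.
#' @export
mcspd_test <- function(dates, curve, window, neolithization = NULL,
                       h = 200, n_sim = 1000L, seed) {
  stopifnot(all(c("site", "cra", "error", "period") %in% names(dates)))
  binned <- bin_dates(dates, h = h)
  observed <- compute_spd(binned, curve, window = window)
  if (is.null(neolithization)) {
    neo <- dates[dates$period == "Neolithic", , drop = FALSE]
    if (!nrow(neo)) stop("no Neolithic dates and no neolithization date given")
    modes <- .cal_modes_c(neo$cra, neo$error, curve$mu, curve$sigma,
                          as.numeric(curve$grid))
    neolithization <- min(max(modes, na.rm = TRUE), max(window))
  }
  null <- fit_null(dates, curve, neolithization, window_old = max(window),
                   h = h)
  ens <- simulate_ensemble(null, n_bins = observed$n_bins,
                           error_pool = dates$error, curve = curve,
                           window = window, n_sim = n_sim, seed = seed)
  env <- mc_envelope(observed, ens)
  gp <- global_pvalue(observed, ens, env = env)
  structure(list(observed = observed, null = null,
                 ensemble = list(rate = ens$rate, n_sim = n_sim,
                                 seed = seed),
                 envelope = list(grid = env$grid, lo = env$lo, hi = env$hi),
                 sig_regions = env$sig_regions, p = gp$p,
                 stat_obs = gp$stat_obs, n_bins = observed$n_bins,
                 neolithization = neolithization),
            class = "mcspd_test")
}

#' @export
print.mcspd_test <- function(x, ...) {
  cat(sprintf(
    "<mcspd_test> N = %d bins; null rate %.4f %%/yr; n_sim = %d\n",
    x$n_bins, 100 * x$ensemble$rate, x$ensemble$n_sim))
  cat(sprintf("  global p-value: %.4g\n", x$p))
  if (nrow(x$sig_regions)) {
    for (i in seq_len(nrow(x$sig_regions)))
      cat(sprintf("  %s envelope: %d-%d cal BP\n",
                  x$sig_regions$direction[i], x$sig_regions$start[i],
                  x$sig_regions$end[i]))
  } else cat("  no excursions outside the 95% envelope\n")
  invisible(x)
}

#' @export
plot.mcspd_test <- function(x, ...) {
  g <- x$envelope$grid
  graphics::plot(g, x$observed$density, type = "n",
                 xlim = rev(range(g)), xlab = "cal BP",
                 ylab = "summed probability", ...)
  graphics::polygon(c(g, rev(g)), c(x$envelope$lo, rev(x$envelope$hi)),
                    col = "grey85", border = NA)
  graphics::lines(g, x$observed$density)
  if (nrow(x$sig_regions)) {
    ab <- x$sig_regions[x$sig_regions$direction == "above", ]
    for (i in seq_len(nrow(ab))) {
      sel <- g <= ab$start[i] & g >= ab$end[i]
      graphics::lines(g[sel], x$observed$density[sel], col = "red", lwd = 2)
    }
  }
  invisible(x)
}

#' Serialise an MCSPD test result
#'
#' Writes the per-year curves (observed, envelope bounds, excursion flags)
#' as CSV and the scalar summary (N, global p, n_sim, seed, null-model
#' parameters) as a JSON sidecar.
#'
#' @param x an `mcspd_test`.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @export
write_mcspd_result <- function(x, stem) {
  stopifnot(inherits(x, "mcspd_test"))
  g <- x$envelope$grid
  above <- rep(FALSE, length(g)); below <- rep(FALSE, length(g))
  for (i in seq_len(nrow(x$sig_regions))) {
    sel <- g <= x$sig_regions$start[i] & g >= x$sig_regions$end[i]
    if (x$sig_regions$direction[i] == "above") above[sel] <- TRUE
    else below[sel] <- TRUE
  }
  utils::write.csv(
    data.frame(cal_bp = g, observed = x$observed$density,
               envelope_lo = x$envelope$lo, envelope_hi = x$envelope$hi,
               above = above, below = below),
    paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_bins = x$n_bins, global_p = x$p, n_sim = x$ensemble$n_sim,
         seed = x$ensemble$seed, null_rate = x$ensemble$rate,
         null_rate_pct = 100 * x$ensemble$rate,
         neolithization = x$neolithization),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
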