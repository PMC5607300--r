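#' Group dates into site-phase bins
#'
#' Dates from the same site whose conventional radiocarbon ages chain
#' together with gaps of at most `h` 14C years are treated as one site
#' phase (single-linkage clustering on the CRA axis, per site). Binning
#' prevents intensively dated sites from dominating the summed
#' distribution: each bin later contributes the average of its member
#' densities, i.e. total mass one.
#'
#' @param dates data.frame with at least `site` and `cra` columns.
#' @param h chaining width in 14C years (default 200). `h = 0` puts every
#'   date in its own bin; `h = Inf` gives one bin per site.
#' @return the input data.frame with a `bin` column added (site label plus
#'   phase index); the number of bins is attached as attribute `n_bins`.
#' @export
bin_dates <- function(dates, h = 200) {
  stopifnot(all(c("site", "cra") %in% names(dates)))
  bin <- character(nrow(dates))
  for (s in unique(dates$site)) {
    idx <- which(dates$site == s)
    o <- idx[order(dates$cra[idx])]
    gaps <- diff(dates$cra[o])
    phase <- cumsum(c(1L, as.integer(gaps > h)))
    bin[o] <- paste0(s, "#", phase)
  }
  dates$bin <- bin
  attr(dates, "n_bins") <- length(unique(bin))
  dates
}

#' Summed Probability Distribution of a set of binned dates
#'
#' Calibrates every date, averages densities within each site-phase bin,
#' and sums the bin densities over the window grid. On the raw scale the
#' total mass equals the number of bins, up to the truncation tails and any
#' mass falling outside the window.
#'
#' @param dates data.frame with `cra`, `error` and a `bin` column (see
#'   [bin_dates()]); a plain date table is binned on the fly with the
#'   default `h`.
#' @param curve a [cal_curve].
#' @param window c(oldest, youngest) cal BP.
#' @param keep_bins if TRUE, per-bin densities are retained (sparse, as
#'   support offset + mass) for bootstrap resampling in
#'   [fit_exponential()].
#' @param trunc tail-mass truncation passed to [calibrate()].
#' @return Object of class `spd`: list with `grid` (ascending cal BP),
#'   `density`, `n_bins`, `scale` ("raw"), `window`, `corrected` flag and
#'   optionally `bin_densities`.
#' @export
compute_spd <- function(dates, curve, window, keep_bins = FALSE,
                        trunc = 1e-5) {
  if (!nrow(dates)) stop("no dates to sum")
  if (!"bin" %in% names(dates)) dates <- bin_dates(dates)
  grid <- seq(min(window), max(window))
  dens <- numeric(length(grid))
  bins <- split(seq_len(nrow(dates)), dates$bin)
  bin_dens <- if (keep_bins) vector("list", length(bins)) else NULL
  for (b in seq_along(bins)) {
    rows <- bins[[b]]
    acc <- numeric(length(grid))
    for (i in rows) {
      cd <- calibrate(dates$cra[i], dates$error[i], curve, trunc = trunc)
      lo <- max(cd$grid[1L], grid[1L])
      hi <- min(cd$grid[length(cd$grid)], grid[length(grid)])
      if (hi < lo) next
      acc[(lo - grid[1L] + 1L):(hi - grid[1L] + 1L)] <-
        acc[(lo - grid[1L] + 1L):(hi - grid[1L] + 1L)] +
        cd$mass[(lo - cd$grid[1L] + 1L):(hi - cd$grid[1L] + 1L)]
    }
    acc <- acc / length(rows)
    dens <- dens + acc
    if (keep_bins) {
      nz <- which(acc > 0)
      bin_dens[[b]] <- if (length(nz))
        list(offset = nz[1L], mass = acc[nz[1L]:nz[length(nz)]]) else
        list(offset = 1L, mass = numeric(0))
    }
  }
  structure(list(grid = grid, density = dens, n_bins = length(bins),
                 scale = "raw", window = c(max(window), min(window)),
                 corrected = FALSE, bin_densities = bin_dens),
            class = "spd")
}

#' Rescale an SPD for cross-region comparison
#'
#' @param spd an `spd` object.
#' @param mode `"per-bin"` divides by the number of bins (total mass ~1);
#'   `"unit-area"` divides by the integral over the window (total mass
#'   exactly 1). Rescaling an already-rescaled SPD in the same mode is a
#'   no-op.
#' @return the rescaled `spd`.
#' @export
rescale_spd <- function(spd, mode = c("per-bin", "unit-area")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spd, "spd"))
  if (identical(spd$scale, mode)) return(spd)
  if (!identical(spd$scale, "raw"))
    stop("can only rescale a raw SPD (current scale: ", spd$scale, ")")
  tot <- sum(spd$density)
  if (tot <= 0) stop("SPD has zero mass; cannot rescale")
  f <- if (mode == "per-bin") 1 / spd$n_bins else 1 / tot
  spd$density <- spd$density * f
  if (!is.null(spd$bin_densities))
    spd$bin_densities <- lapply(spd$bin_densities, function(b) {
      b$mass <- b$mass * f; b
    })
  spd$scale <- mode
  spd
}

# Taphonomic survival model: expected surviving fraction of the record at
# age t (cal BP), a power-law loss curve. Dividing an SPD by this curve
# removes the systematic under-representation of older material.
taphonomic_survival <- function(t) {
  5726442 * (t + 2176.4)^(-1.3925309)
}

#' Correct an SPD for taphonomic loss
#'
#' Divides the density by the power-law survival curve
#' n(t) = 5,726,442 (t + 2,176.4)^(-1.3925309) and renormalises so the
#' total mass is preserved. Because survival decreases with age, the
#' correction shifts mass toward older calendar years.
#'
#' @param spd an `spd` object.
#' @return the corrected `spd` (flag `corrected = TRUE`).
#' @export
correct_taphonomy <- function(spd) {
  stopifnot(inherits(spd, "spd"))
  if (spd$corrected) return(spd)
  tot <- sum(spd$density)
  d <- spd$density / taphonomic_survival(spd$grid)
  spd$density <- d * (tot / sum(d))
  spd$bin_densities <- NULL   # member densities no longer sum to the SPD
  spd$corrected <- TRUE
  spd
}

#' Fit an exponential growth model to an SPD
#'
#' Fits density(t) = C exp(-r t), with t in cal BP, by nonlinear least
#' squares over the requested window (r > 0 means growth toward the
#' present; the annual growth rate is e^r - 1 ~ r). Start values come from
#' a log-linear regression on the positive cells. The standard error is
#' estimated by resampling site-phase bins with replacement (`n_boot`
#' refits); with `n_boot = 0` the asymptotic NLS standard error is
#' returned instead.
#'
#' @param spd an `spd` object (with `bin_densities` kept if a bootstrap SE
#'   is wanted).
#' @param window c(oldest, youngest) cal BP fit range; defaults to the SPD
#'   window.
#' @param n_boot bootstrap replicates for the SE (default 200).
#' @param seed optional seed for the bootstrap, applied to a local RNG
#'   state.
#' @return Object of class `growth_fit`: list with `rate` (fraction/yr),
#'   `rate_pct` (percent/yr), `se`, `se_pct`, `C`, `window`, `n_boot`,
#'   `corrected` (inherited from the SPD).
#' @export
fit_exponential <- function(spd, window = NULL, n_boot = 200, seed = NULL) {
  stopifnot(inherits(spd, "spd"))
  if (is.null(window)) window <- spd$window
  sel <- spd$grid >= min(window) & spd$grid <= max(window)
  t <- spd$grid[sel]; y <- spd$density[sel]
  if (sum(y > 0) <= 10L)
    stop("fewer than 10 positive SPD cells in the fit window")
  fit <- fit_exp_curve(t, y)
  se <- se_pct <- NA_real_
  if (n_boot > 0 && !is.null(spd$bin_densities)) {
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
      } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
      }
      set.seed(seed)
    }
    nb <- length(spd$bin_densities)
    ng <- length(spd$grid)
    # bootstrap over bins == multinomial resampling weights; when the
    # dense bin-by-grid matrix fits comfortably, one BLAS multiply gives
    # all bootstrap SPDs at once
    counts <- stats::rmultinom(n_boot, nb, rep(1, nb))
    boot_spds <- if (nb * ng <= 3e7) {
      M <- matrix(0, nrow = nb, ncol = ng)
      for (b in seq_len(nb)) {
        bd <- spd$bin_densities[[b]]
        if (length(bd$mass))
          M[b, bd$offset:(bd$offset + length(bd$mass) - 1L)] <- bd$mass
      }
      crossprod(M, counts)
    } else {
      out <- matrix(0, nrow = ng, ncol = n_boot)
      for (b in seq_len(nb)) {
        bd <- spd$bin_densities[[b]]
        if (!length(bd$mass)) next
        ix <- bd$offset:(bd$offset + length(bd$mass) - 1L)
        out[ix, ] <- out[ix, ] + outer(bd$mass, counts[b, ])
      }
      out
    }
    rates <- vapply(seq_len(n_boot), function(i) {
      fb <- try(fit_exp_curve(t, boot_spds[sel, i]), silent = TRUE)
      if (inherits(fb, "try-error")) NA_real_ else fb$rate
    }, 0.0)
    se <- stats::sd(rates, na.rm = TRUE)
    se_pct <- 100 * se
  } else if (n_boot == 0) {
    se <- fit$se_asymptotic
    se_pct <- 100 * se
  }
  structure(list(rate = fit$rate, rate_pct = 100 * fit$rate, se = se,
                 se_pct = se_pct, C = fit$C,
                 window = c(max(window), min(window)), n_boot = n_boot,
                 corrected = spd$corrected),
            class = "growth_fit")
}

# Core exponential fit: nonlinear least squares with log-linear start.
fit_exp_curve <- function(t, y) {
  pos <- y > max(y) * 1e-9
  if (sum(pos) <= 10L) stop("too few positive cells for exponential fit")
  # start values from log-linear regression, weighted by density
  lf <- stats::lm(log(y[pos]) ~ t[pos], weights = y[pos])
  r0 <- -unname(stats::coef(lf)[2L])
  c0 <- exp(unname(stats::coef(lf)[1L]))
  df <- data.frame(t = t, y = y)
  fit <- minpack.lm::nlsLM(y ~ C * exp(-r * t), data = df,
                           start = list(C = c0, r = r0),
                           control = minpack.lm::nls.lm.control(maxiter = 100))
  cf <- stats::coef(fit)
  se_r <- tryCatch(sqrt(stats::vcov(fit)["r", "r"]), error = function(e) NA_real_)
  list(rate = unname(cf["r"]), C = unname(cf["C"]), se_asymptotic = se_r)
}

#' Evaluate a fitted exponential null on a calendar grid
#'
#' @param fit a `growth_fit`.
#' @param grid calendar ages (cal BP).
#' @return expected density at each grid year.
#' @export
predict_exponential <- function(fit, grid) {
  stopifnot(inherits(fit, "growth_fit"))
  fit$C * exp(-fit$rate * grid)
}

#' @export
print.spd <- function(x, ...) {
  cat("<spd> ", x$window[1L], "-", x$window[2L], " cal BP; ",
      x$n_bins, " bins; scale ", x$scale,
      if (x$corrected) "; taphonomically corrected" else "",
      "; total mass ", format(signif(sum(x$density), 6)), "\n", sep = "")
  invisible(x)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> rate %.4f %%/yr (SE %s) over %d-%d cal BP%s\n",
              x$rate_pct,
              if (is.na(x$se_pct)) "n/a" else sprintf("%.4f", x$se_pct),
              x$window[1L], x$window[2L],
              if (x$corrected) " [taphonomy-corrected]" else ""))
  invisible(x)
}

#' @export
plot.spd <- function(x, add = FALSE, col = "black", ...) {
  if (!add)
    graphics::plot(x$grid, x$density, type = "l", col = col,
                   xlim = rev(range(x$grid)), xlab = "cal BP",
                   ylab = "summed probability", ...)
  else graphics::lines(x$grid, x$density, col = col, ...)
  invisible(x)
}
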