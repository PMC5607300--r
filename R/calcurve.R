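#' Construct a calibration curve object
#'
#' A calibration curve maps calendar age (cal BP, years before 1950) to the
#' expected conventional radiocarbon age and its 1-sigma curve uncertainty.
#' The tabulated curve is linearly interpolated onto a 1-year calendar grid,
#' the resolution at which all calibrated densities are evaluated.
#'
#' @param cal_bp numeric vector of calendar ages (cal BP). Need not be sorted,
#'   but must contain no duplicates.
#' @param c14_bp expected radiocarbon age (14C yr BP) at each `cal_bp`.
#' @param error 1-sigma curve error (14C yr) at each `cal_bp`; must be >= 0.
#' @param name curve label.
#' @return An object of class `cal_curve`: a list with integer `grid`
#'   (ascending cal BP, 1-yr step), `mu`, `sigma` (both interpolated to the
#'   grid) and `name`.
#' @examples
#' crv <- cal_curve(c(1000, 2000), c(1100, 2050), c(10, 12))
#' curve_at(crv, 1500)  # mu = 1575, sigma = 11
#' @export
cal_curve <- function(cal_bp, c14_bp, error, name = "custom") {
  stopifnot(length(cal_bp) == length(c14_bp), length(cal_bp) == length(error))
  if (length(cal_bp) < 2L)
    stop("a calibration curve needs at least two tabulated points")
  if (anyDuplicated(cal_bp))
    stop("duplicated calendar ages in calibration curve")
  if (any(!is.finite(c14_bp)))
    stop("non-finite radiocarbon ages in calibration curve")
  if (any(error < 0))
    stop("negative curve errors in calibration curve")
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]; c14_bp <- c14_bp[o]; error <- error[o]
  grid <- seq(ceiling(cal_bp[1L]), floor(cal_bp[length(cal_bp)]), by = 1)
  structure(list(
    grid  = as.integer(grid),
    mu    = stats::approx(cal_bp, c14_bp, xout = grid)$y,
    sigma = stats::approx(cal_bp, error, xout = grid)$y,
    name  = name
  ), class = "cal_curve")
}

#' Read a tabulated calibration curve file
#'
#' Reads the plain-text dialect used by the IntCal family of curves: comment
#' lines starting with `#`, then rows of at least three numeric columns
#' (cal BP, 14C age BP, 1-sigma error, ...), separated by commas or
#' whitespace. Both delimiters are tolerated. The curve is interpolated to a
#' 1-year grid over the file's span.
#'
#' @param path path to the curve file.
#' @param name curve label; defaults to the file name.
#' @return A [cal_curve] object.
#' @export
read_cal_curve <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in curve file: ", path)
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "[,[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 3L || anyNA(vals[1:3]))
      stop("malformed row at data line ", i, " of ", path, ": '",
           lines[[i]], "'")
    vals[1:3]
  })
  m <- do.call(rbind, rows)
  cb <- m[, 1L]
  ord <- diff(cb)
  if (!(all(ord > 0) || all(ord < 0)))
    stop("cal BP column of ", path, " is not monotone")
  cal_curve(cb, m[, 2L], m[, 3L], name = name)
}

#' Write a calibration curve in the tabulated text dialect
#'
#' Inverse of [read_cal_curve()]; used mainly to exercise the reader on
#' synthetic curves. Columns: cal BP, 14C age, error (comma separated,
#' descending cal BP as in the published files).
#'
#' @param curve a [cal_curve] object.
#' @param path output file.
#' @param thin write every `thin`-th grid year (the published curves tabulate
#'   at coarser-than-annual spacing; the reader re-interpolates).
#' @export
write_cal_curve <- function(curve, path, thin = 5L) {
  idx <- seq(length(curve$grid), 1L, by = -thin)
  if (idx[length(idx)] != 1L) idx <- c(idx, 1L)
  hdr <- c(paste0("# ", curve$name), "# cal BP, 14C age BP, error")
  rows <- sprintf("%d,%.2f,%.2f", curve$grid[idx], curve$mu[idx],
                  curve$sigma[idx])
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Evaluate a calibration curve at calendar ages
#'
#' @param curve a [cal_curve].
#' @param t calendar ages (cal BP) within the curve span.
#' @return list with components `mu` and `sigma` at `t` (linear
#'   interpolation between grid years).
#' @export
curve_at <- function(curve, t) {
  if (any(t < curve$grid[1L] | t > curve$grid[length(curve$grid)]))
    stop("calendar age outside calibration curve span")
  list(mu    = stats::approx(curve$grid, curve$mu, xout = t)$y,
       sigma = stats::approx(curve$grid, curve$sigma, xout = t)$y)
}

#' Calibrate a radiocarbon determination
#'
#' Converts a conventional radiocarbon age (CRA) and its laboratory error
#' into a probability mass function over the calendar grid of the curve.
#' The measurement model is the standard intercept-free Gaussian: the mass at
#' calendar year t is proportional to the normal density of `cra` about
#' mu(t) with variance `error`^2 + sigma(t)^2. The density is normalised to
#' total mass 1, then its support is truncated to the smallest contiguous
#' grid window holding at least `1 - trunc` of the mass and renormalised.
#'
#' @param cra conventional radiocarbon age (14C yr BP), scalar.
#' @param error 1-sigma laboratory error (14C yr), > 0.
#' @param curve a [cal_curve].
#' @param trunc total tail mass removed when truncating the support
#'   (default 1e-5); `trunc = 0` keeps the full curve grid.
#' @return Object of class `cal_density`: list with `grid` (ascending cal BP
#'   integers), `mass` (sums to 1), `mode` (cal BP of the maximum-mass year,
#'   ties broken toward the older age), `cra`, `error`.
#' @examples
#' ident <- cal_curve(c(0, 10000), c(0, 10000), c(0, 0))
#' d <- calibrate(5000, 50, ident)
#' d$mode  # 5000
#' @export
calibrate <- function(cra, error, curve, trunc = 1e-5) {
  stopifnot(length(cra) == 1L, length(error) == 1L)
  if (!is.finite(cra)) stop("non-finite radiocarbon age")
  if (error <= 0) stop("laboratory error must be positive")
  s <- sqrt(error^2 + curve$sigma^2)
  span_sd <- 10 * max(s)
  if (cra < min(curve$mu) - span_sd || cra > max(curve$mu) + span_sd)
    stop("radiocarbon age ", cra, " outside calibration curve span")
  w <- stats::dnorm(cra, mean = curve$mu, sd = pmax(s, .Machine$double.eps))
  tot <- sum(w)
  if (tot <= 0) stop("calibrated density has zero mass")
  mass <- w / tot
  keep <- c(1L, length(mass))
  if (trunc > 0) keep <- min_mass_window(mass, 1 - trunc)
  grid <- curve$grid[keep[1L]:keep[2L]]
  mass <- mass[keep[1L]:keep[2L]]
  mass <- mass / sum(mass)
  structure(list(grid = grid, mass = mass, mode = mode_of_mass(grid, mass),
                 cra = cra, error = error),
            class = "cal_density")
}

# Smallest contiguous index window [i, j] with sum(mass[i:j]) >= target.
# For each start i the smallest admissible end is found in one vectorised
# findInterval pass; ties resolve to the first (youngest-starting) window.
min_mass_window <- function(mass, target) {
  n <- length(mass)
  cum <- cumsum(mass)
  lo <- c(0, cum[-n])
  j <- findInterval(lo + target, cum, left.open = TRUE) + 1L
  len <- ifelse(j <= n, j - seq_len(n) + 1L, NA_integer_)
  i <- which.min(len)
  c(i, j[i])
}

mode_of_mass <- function(grid, mass) {
  mx <- max(mass)
  # tie-break toward the older (larger cal BP) year
  max(grid[mass >= mx - .Machine$double.eps * mx])
}

#' Mode of a calibrated density
#'
#' The calendar year carrying the maximum probability mass; exact ties are
#' broken toward the older (larger cal BP) year so that front tracking sees
#' a deterministic earliest arrival.
#'
#' @param density a `cal_density` from [calibrate()].
#' @return scalar cal BP.
#' @export
cal_mode <- function(density) {
  stopifnot(inherits(density, "cal_density"))
  density$mode
}

#' Draw a synthetic radiocarbon measurement for a known calendar age
#'
#' The inverse of calibration, used by the Monte-Carlo machinery: for a true
#' calendar age the CRA is drawn as mu(t) plus Gaussian noise with the
#' laboratory and curve variances added in quadrature. The curve error
#' enters here, in a single draw, and is therefore not double-counted when
#' the simulated date is later recalibrated.
#'
#' @param t_true calendar ages (cal BP) within the curve span; vectorised.
#' @param curve a [cal_curve].
#' @param error 1-sigma laboratory error(s), recycled against `t_true`.
#' @param seed optional integer; when given, the draw is made under a local
#'   RNG state seeded with it (the caller's RNG stream is untouched) so a
#'   recorded seed reproduces the measurement exactly.
#' @return data.frame with columns `cra` and `error`.
#' @export
uncalibrate <- function(t_true, curve, error, seed = NULL) {
  at <- curve_at(curve, t_true)   # errors if out of span
  error <- rep_len(error, length(t_true))
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  sd_tot <- sqrt(at$sigma^2 + error^2)
  data.frame(cra = at$mu + stats::rnorm(length(t_true), 0, sd_tot),
             error = error)
}

#' @export
print.cal_curve <- function(x, ...) {
  cat("<cal_curve> ", x$name, ": ", x$grid[1L], "-",
      x$grid[length(x$grid)], " cal BP (1-yr grid, ",
      length(x$grid), " years)\n", sep = "")
  invisible(x)
}

#' @export
print.cal_density <- function(x, ...) {
  cat("<cal_density> CRA ", x$cra, " +/- ", x$error,
      "; mode ", x$mode, " cal BP; support ", x$grid[1L], "-",
      x$grid[length(x$grid)], " cal BP\n", sep = "")
  invisible(x)
}
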