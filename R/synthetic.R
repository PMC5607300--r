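#' A smooth monotone toy calibration curve
#'
#' Identity mapping plus a low-amplitude sinusoidal wiggle, with a mildly
#' age-dependent curve error. The wiggle keeps calibration non-trivial
#' (densities are locally compressed and stretched) while the curve stays
#' strictly monotone, hence invertible, which the simulation machinery
#' requires. Amplitude and period default to values comparable to the
#' decadal-to-centennial structure of the published curves.
#'
#' @param span c(young, old) cal BP extent of the curve.
#' @param amplitude wiggle amplitude in 14C yr (keep below `period/(2*pi)`
#'   for monotonicity; default 25).
#' @param period wiggle period in calendar years (default 900).
#' @param sigma0 curve error at 0 cal BP (14C yr).
#' @param sigma_slope increase of curve error per calendar year.
#' @return a [cal_curve].
#' @export
toy_curve <- function(span = c(0, 14600), amplitude = 25, period = 900,
                      sigma0 = 10, sigma_slope = 1 / 1500) {
  if (amplitude * 2 * pi / period >= 1)
    stop("wiggle amplitude too large: curve would be non-monotone")
  t <- seq(min(span), max(span))
  cal_curve(t, t + amplitude * sin(2 * pi * t / period),
            sigma0 + sigma_slope * t, name = "toy")
}

#' Configuration of a synthetic wave-of-advance world
#'
#' Defines the ground truth for [generate_world()]: a farming package
#' establishes itself in an origin disc, then expands radially in discrete
#' pulses separated by pauses, sweeping over a background of forager
#' (Mesolithic) sites. Each concentric ring carved out by a pulse follows
#' one of three demographic regimes: 1 — a persistent carrying-capacity
#' boost with faster growth (the innovation centre and its surroundings);
#' 2 — a transient boom at the passage of the travelling front, relaxing
#' back to the forager trend after the front departs (sparse forager
#' background, incoming colonist sites); 3 — adoption by a dense forager
#' population: the existing site network converts to farming at arrival
#' and its date intensity continues the forager trend unchanged, so the
#' regional record shows no demographic deviation. Forager site density
#' per ring is derived from the regime: dense where regime 3, sparse
#' elsewhere, with a separate density for the origin disc. Colonist sites
#' (regime-1/2 rings only) additionally receive a founding-phase cluster
#' of dates just after first arrival, reflecting the preferential dating
#' of pioneer settlement contexts.
#'
#' The default pulse schedule uses six expansion pulses between 10,900 and
#' 6,000 cal BP with speeds in the 0.5-2.5 km/yr range and pauses of at
#' least 400 years. Pauses much shorter than that are unresolvable by
#' 100-yr hull stepping once laboratory errors approach 100 14C yr: a
#' ring's hull expression is smeared over roughly two hull steps by mode
#' noise and the founding-date lag, so consecutive pulses closer than ~400
#' years merge into one detected episode whatever the detector settings.
#'
#' @param seed integer seed (mandatory: worlds must be reproducible).
#' @param n_dates expected number of trend (intensity-driven) dates; the
#'   founding-phase and adoption-horizon dates are drawn per site and come
#'   on top of this target.
#' @param origin c(lon, lat) of the innovation centre.
#' @param origin_radius radius of the founding disc (km).
#' @param origin_start cal BP at which farming appears at the centre of the
#'   origin disc (spreads across the disc at 2.5 km/yr).
#' @param pulse_schedule data.frame with `start`, `end` (cal BP; the front
#'   moves during \[start, end\]) and `speed` (km/yr) per pulse.
#' @param regimes integer vector of regime labels (1/2/3), one for the
#'   origin disc followed by one per pulse ring.
#' @param meso_rate,neo_rate annual growth rates (fraction/yr) of the
#'   forager background and of regime-1 farming populations.
#' @param boost persistent intensity multiplier at farming arrival in
#'   regime-1 rings.
#' @param boom peak intensity multiplier at front passage in regime-2
#'   rings.
#' @param boom_relax e-folding time (yr) of the post-departure relaxation
#'   of the boom.
#' @param meso_density forager sites per 10^4 km^2, c(low, high); regime-3
#'   rings use `high`, all others `low`.
#' @param meso_weight date-intensity multiplier for forager sites
#'   relative to farming sites, reflecting the richer per-site sampling of
#'   Mesolithic contexts needed to anchor regional null models.
#' @param origin_meso_density forager site density in the origin disc.
#' @param neo_site_density colonist sites per 10^4 km^2 in regime-1/2
#'   rings outside the origin disc.
#' @param origin_neo_density colonist site density in the origin disc.
#' @param founding_prob probability that a colonist site carries a
#'   founding-phase date cluster.
#' @param adoption_prob probability that a converted forager site in a
#'   regime-3 ring carries one extra date from its adoption horizon (the
#'   stratigraphic transition to farming, a preferentially dated context).
#' @param founding_lag minimum delay (yr) between first arrival and the
#'   earliest datable founding context.
#' @param founding_span width (yr) of the founding window beyond
#'   `founding_lag` over which founding dates are spread.
#' @param error_range range of emitted 1-sigma laboratory errors (14C yr).
#' @param frac_oversized fraction of dates given errors in (150, 250\] so
#'   that downstream filtering of the 150-yr error cap is exercised.
#' @param gen_range c(old, young) cal BP range of emitted true ages
#'   (slightly wider than the analysis brackets so bracket filtering is
#'   exercised too).
#' @return list of class `world_config`.
#' @export
world_config <- function(seed,
                         n_dates = 6000,
                         origin = c(35, 36),
                         origin_radius = 300,
                         origin_start = 11700,
                         pulse_schedule = data.frame(
                           start = c(10900, 9900, 9100, 8100, 7300, 6400),
                           end   = c(10500, 9500, 8600, 7700, 6900, 6000),
                           speed = c(1.0, 1.0, 1.0, 1.5, 1.0, 1.25)),
                         regimes = c(1, 1, 2, 2, 2, 3, 3),
                         meso_rate = 3e-4,
                         neo_rate = 5e-4,
                         boost = 2.5,
                         boom = 6,
                         boom_relax = 300,
                         meso_density = c(low = 0.05, high = 0.8),
                         meso_weight = 2,
                         origin_meso_density = 1.2,
                         neo_site_density = 0.3,
                         origin_neo_density = 0.6,
                         founding_prob = 1,
                         adoption_prob = 0.15,
                         founding_lag = 60,
                         founding_span = 80,
                         error_range = c(20, 120),
                         frac_oversized = 0,
                         gen_range = c(12600, 4800)) {
  if (missing(seed)) stop("world_config requires a seed")
  stopifnot(nrow(pulse_schedule) >= 1L,
            all(pulse_schedule$start > pulse_schedule$end |
                  pulse_schedule$speed == 0),
            length(regimes) == nrow(pulse_schedule) + 1L,
            all(regimes %in% 1:3))
  structure(as.list(environment()), class = "world_config")
}

# Cumulative front radii: origin disc edge, then one entry per pulse.
front_radii <- function(cfg) {
  w <- with(cfg$pulse_schedule, speed * (start - end))
  cumsum(c(cfg$origin_radius, w))
}

# First-arrival time of farming at distance d (km) from the origin;
# -Inf-like (NA) where the front never reaches.
arrival_time <- function(cfg, d) {
  radii <- front_radii(cfg)
  ps <- cfg$pulse_schedule
  arr <- rep(NA_real_, length(d))
  in_origin <- d <= radii[1L]
  arr[in_origin] <- cfg$origin_start - d[in_origin] / 2.5
  for (k in seq_len(nrow(ps))) {
    sel <- d > radii[k] & d <= radii[k + 1L]
    if (ps$speed[k] > 0)
      arr[sel] <- ps$start[k] - (d[sel] - radii[k]) / ps$speed[k]
  }
  arr
}

ring_of <- function(cfg, d) {
  radii <- front_radii(cfg)
  r <- findInterval(d, radii, left.open = TRUE)   # 0 = origin disc
  r[d > radii[length(radii)]] <- NA_integer_
  r
}

#' Generate a ground-truthed synthetic radiocarbon dataset
#'
#' Simulates the world described by a [world_config()]: forager sites are
#' scattered per ring at their regime-dependent density and emit
#' Mesolithic dates with exponential intensity until farming arrives at
#' their location; farming sites emit Neolithic dates from their
#' first-arrival time with the regime's intensity profile (boost, boom, or
#' forager-trend continuation, the latter amplitude-matched to the ring's
#' forager record so regime-3 rings show no demographic deviation). True
#' calendar ages are converted to radiocarbon measurements through the toy
#' curve with the laboratory and curve errors drawn in quadrature.
#' Everything is drawn under the configuration seed, so regeneration is
#' byte-identical.
#'
#' @param cfg a `world_config`.
#' @param curve a [cal_curve] spanning the generation range; default
#'   [toy_curve()].
#' @return list of class `synthetic_world`: `dates` (data.frame with
#'   `lab_code`, `cra`, `error`, `site`, `lon`, `lat`, `period`,
#'   `culture`), `truth` (list with per-date data.frame `dates` —
#'   `true_age`, `ring`, `regime`, `dist_km` — and per-ring data.frame
#'   `rings`), `curve`, `config`.
#' @export
generate_world <- function(cfg, curve = toy_curve()) {
  stopifnot(inherits(cfg, "world_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(cfg$seed)

  radii <- front_radii(cfg)
  nring <- length(radii) - 1L          # pulse rings; ring 0 is the disc
  ps <- cfg$pulse_schedule
  t_old <- max(cfg$gen_range); t_young <- min(cfg$gen_range)
  tgrid <- seq(t_old, t_young)

  # site placement -------------------------------------------------------
  place_sites <- function(r_in, r_out, density, prefix) {
    area <- pi * (r_out^2 - r_in^2)
    n <- stats::rpois(1L, density * area / 1e4)
    if (n == 0L) return(NULL)
    d <- sqrt(stats::runif(n, r_in^2, r_out^2))
    brg <- stats::runif(n, 0, 360)
    ll <- geosphere::destPoint(cfg$origin, brg, d * 1000)
    data.frame(site = sprintf("%s-%03d", prefix, seq_len(n)),
               lon = ll[, 1L], lat = ll[, 2L], dist = d, bearing = brg)
  }
  ring_regime <- cfg$regimes            # index 1 = origin disc (ring 0)
  meso_sites <- list(); neo_sites <- list()
  for (r in 0:nring) {
    r_in <- if (r == 0L) 0 else radii[r]
    r_out <- radii[r + 1L]
    if (r_out <= r_in) next
    reg <- ring_regime[r + 1L]
    dm <- if (r == 0L) cfg$origin_meso_density
          else if (reg == 3L) cfg$meso_density[["high"]]
          else cfg$meso_density[["low"]]
    ms <- place_sites(r_in, r_out, dm, sprintf("M%d", r))
    if (!is.null(ms)) { ms$ring <- r; meso_sites[[length(meso_sites) + 1L]] <- ms }
    if (reg != 3L) {  # colonists settle only where foragers are sparse
      dn <- if (r == 0L) cfg$origin_neo_density else cfg$neo_site_density
      ns <- place_sites(r_in, r_out, dn, sprintf("N%d", r))
      if (!is.null(ns)) { ns$ring <- r; neo_sites[[length(neo_sites) + 1L]] <- ns }
    }
  }
  meso_sites <- do.call(rbind, meso_sites)
  neo_sites <- do.call(rbind, neo_sites)
  if (is.null(neo_sites) || !nrow(neo_sites))
    stop("infeasible configuration: no farming sites placed")
  meso_sites$arrival <- arrival_time(cfg, meso_sites$dist)
  neo_sites$arrival <- arrival_time(cfg, neo_sites$dist)
  # ring departure: moment the front leaves the ring (pulse end)
  departure <- c(cfg$origin_start - cfg$origin_radius / 2.5, ps$end)

  # per-site intensity weights on the calendar grid ----------------------
  # Forager sites follow exp(-meso_rate * t). In regime-3 rings the same
  # sites keep that trend across farming arrival (adoption: only the
  # period label changes); elsewhere forager occupation ends at arrival.
  # Colonist sites are active after arrival: in regime-1 rings at a
  # persistently boosted level growing at neo_rate, in regime-2 rings at
  # the ring's forager-trend level times the boom factor (peak while the
  # front dwells in the ring, exponential relaxation after it departs).
  n_m_ring <- tabulate(meso_sites$ring + 1L, nbins = nring + 1L)
  n_n_ring <- tabulate(neo_sites$ring + 1L, nbins = nring + 1L)
  cont <- ifelse(n_n_ring > 0, pmax(n_m_ring, 1) / n_n_ring, 0)

  site_weights <- function(s, kind) {
    w <- exp(-cfg$meso_rate * tgrid)
    reg <- ring_regime[s$ring + 1L]
    if (kind == "forager") {
      if (is.na(s$arrival) || reg == 3L) return(cfg$meso_weight * w)
      return(cfg$meso_weight * w * (tgrid >= s$arrival))
    }
    if (is.na(s$arrival)) return(numeric(length(tgrid)))
    active <- tgrid <= s$arrival
    alpha <- cont[s$ring + 1L]
    if (reg == 1L) {
      w <- alpha * cfg$boost * exp(-cfg$meso_rate * s$arrival) *
        exp(cfg$neo_rate * (s$arrival - tgrid))
    } else {
      dep <- departure[s$ring + 1L]
      bf <- ifelse(tgrid >= dep, cfg$boom,
                   1 + (cfg$boom - 1) * exp(-(dep - tgrid) / cfg$boom_relax))
      w <- alpha * w * bf
    }
    w * active
  }

  sites <- rbind(cbind(meso_sites, kind = "forager"),
                 cbind(neo_sites, kind = "colonist"))
  W <- lapply(seq_len(nrow(sites)), function(i)
    site_weights(sites[i, ], sites$kind[i]))
  totals <- vapply(W, sum, 0.0)
  if (sum(totals) <= 0) stop("infeasible configuration: zero date intensity")

  # founding-phase dates at colonist sites, adoption-horizon dates at
  # converted forager sites ----------------------------------------------
  found <- list()
  for (i in seq_len(nrow(sites))) {
    if (is.na(sites$arrival[i])) next
    reg <- ring_regime[sites$ring[i] + 1L]
    if (sites$kind[i] == "colonist") {
      if (stats::runif(1) > cfg$founding_prob) next
      nf <- 1L + stats::rpois(1L, 1.2)
      lag <- cfg$founding_lag
    } else if (reg == 3L) {
      if (stats::runif(1) > cfg$adoption_prob) next
      nf <- 1L
      lag <- 0     # the adoption horizon dates the transition itself
    } else next
    ages <- round(sites$arrival[i] - lag -
                    stats::runif(nf, 0, cfg$founding_span))
    ages <- pmin(pmax(ages, t_young), t_old)
    found[[length(found) + 1L]] <- data.frame(i = i, age = ages)
  }
  found <- do.call(rbind, found)
  n_found <- if (is.null(found)) 0L else nrow(found)
  scale <- max(cfg$n_dates - n_found, 1) / sum(totals)

  # draw intensity-driven dates ------------------------------------------
  emit <- function(i, ages) {
    reg <- ring_regime[sites$ring[i] + 1L]
    period <- if (sites$kind[i] == "colonist") "Neolithic"
      else if (reg == 3L && !is.na(sites$arrival[i]))
        ifelse(ages >= sites$arrival[i], "Mesolithic", "Neolithic")
      else "Mesolithic"
    data.frame(
      site = sites$site[i], lon = sites$lon[i], lat = sites$lat[i],
      period = period,
      culture = if (sites$bearing[i] < 180) "eastern" else "western",
      true_age = ages, ring = sites$ring[i], regime = reg,
      dist_km = sites$dist[i])
  }
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    n_i <- stats::rpois(1L, scale * totals[i])
    if (n_i == 0L) next
    rows[[i]] <- emit(i, sample(tgrid, n_i, replace = TRUE, prob = W[[i]]))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (n_found > 0L)
    rows <- c(rows, lapply(unique(found$i), function(i)
      emit(i, found$age[found$i == i])))
  dd <- do.call(rbind, rows)
  if (is.null(dd) || !nrow(dd)) stop("infeasible configuration: no dates")

  # radiocarbon measurement ----------------------------------------------
  n <- nrow(dd)
  err <- stats::runif(n, cfg$error_range[1L], cfg$error_range[2L])
  if (cfg$frac_oversized > 0) {
    big <- stats::runif(n) < cfg$frac_oversized
    err[big] <- stats::runif(sum(big), 151, 250)
  }
  at <- curve_at(curve, dd$true_age)
  cra <- at$mu + stats::rnorm(n, 0, sqrt(at$sigma^2 + err^2))

  dates <- data.frame(
    lab_code = sprintf("SYN-%05d", seq_len(n)),
    cra = round(cra, 1), error = round(err),
    site = dd$site, lon = dd$lon, lat = dd$lat,
    period = dd$period, culture = dd$culture,
    stringsAsFactors = FALSE)
  truth_dates <- data.frame(
    lab_code = dates$lab_code, true_age = dd$true_age, ring = dd$ring,
    regime = dd$regime, dist_km = dd$dist_km, period = dd$period)
  truth_rings <- data.frame(
    ring = 0:nring,
    regime = ring_regime,
    r_inner = c(0, radii[-length(radii)]),
    r_outer = radii,
    arrival = c(cfg$origin_start, ps$start),
    departure = departure,
    meso_sites = n_m_ring, neo_sites = n_n_ring)
  structure(list(dates = dates,
                 truth = list(dates = truth_dates, rings = truth_rings,
                              meso_rate = cfg$meso_rate,
                              neo_rate = cfg$neo_rate),
                 curve = curve, config = cfg),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world> seed ", x$config$seed, ": ", nrow(x$dates),
      " dates (", sum(x$dates$period == "Mesolithic"), " Mesolithic, ",
      sum(x$dates$period == "Neolithic"), " Neolithic) across ",
      length(unique(x$dates$site)), " sites, ",
      nrow(x$truth$rings), " rings\n", sep = "")
  invisible(x)
}

#' Write a synthetic world to disk in the real input formats
#'
#' Emits `dates.csv` in the standard date-table schema (`lab_code`, `cra`,
#' `sigma_lab`, `site`, `lon`, `lat`, `period`, `culture`), the toy curve
#' in the tabulated curve dialect (`curve.14c`) and the ground truth as
#' JSON (`truth.json`), so the package's own readers are exercised on
#' synthetic output.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- world$dates
  names(d)[names(d) == "error"] <- "sigma_lab"
  utils::write.csv(d, file.path(dir, "dates.csv"), row.names = FALSE)
  write_cal_curve(world$curve, file.path(dir, "curve.14c"))
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Configuration of the textbook three-regime study world
#'
#' A compact three-pulse world exhibiting all three demographic regimes,
#' used for classification studies: the origin disc carries a persistent
#' carrying-capacity boost (regime 1), the first two pulse rings receive
#' colonist booms in sequence (regime 2, so boom staggering is testable)
#' and the outer ring is a dense forager landscape that adopts farming
#' with no demographic deviation (regime 3). Forager densities are higher
#' than in the default world so that every region holds enough Mesolithic
#' site phases to anchor its null model.
#'
#' @param seed integer seed.
#' @param n_dates expected total number of dates.
#' @return a [world_config()].
#' @export
three_regime_config <- function(seed, n_dates = 2200) {
  world_config(
    seed = seed, n_dates = n_dates,
    origin_start = 10600,
    pulse_schedule = data.frame(start = c(9800, 8600, 7400),
                                end   = c(9300, 8200, 7000),
                                speed = c(1.0, 1.25, 1.0)),
    regimes = c(1, 2, 2, 3),
    meso_density = c(low = 0.2, high = 0.8),
    origin_meso_density = 5,
    meso_weight = 4,
    adoption_prob = 0)
}
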