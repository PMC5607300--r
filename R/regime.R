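#' Run the full pipeline on a synthetic world and score regime recovery
#'
#' Executes every stage on a generated world — error and bracket
#' filtering, calibration and mode extraction, hull-series front tracking,
#' pulse detection, regionalisation, per-region Monte-Carlo SPD tests —
#' and classifies each recovered region into one of the three demographic
#' regimes, then scores the classification against the generator's ground
#' truth.
#'
#' Classification rule (region-level, using only pipeline outputs): let
#' the post-arrival window run from the region's Neolithization date to
#' the young bracket plus an edge margin. A region deviates when the
#' global p-value is below `alpha`, the observed SPD escapes above the
#' 95% envelope within that window, and the excursion is substantial —
#' its peak exceeds the envelope by at least the factor `excess_ratio`
#' (high-N regions can cross a tight envelope with deviations far too
#' small to constitute a demographic boom; such regions still follow the
#' forager trend). A deviating origin region is always a persistent trend
#' change (regime 1): no travelling front ever passes through the origin
#' — dispersal starts there — so a deviation at the innovation centre
#' cannot be a front transient. Elsewhere, a deviation covering at least
#' `sustained_frac` of the window is regime 1, otherwise a transient boom
#' (regime 2); everything else is regime 3. A region is matched to truth
#' through its pulse index (ring k of the generator).
#'
#' @param world a `synthetic_world`.
#' @param n_sim ensemble size per regional test (default 500).
#' @param seed integer; region k is tested with seed `seed + k`.
#' @param h site-phase binning width (14C yr).
#' @param alpha significance level of the global p-value.
#' @param sustained_frac coverage fraction separating persistent (regime
#'   1) from transient (regime 2) deviations.
#' @param excess_ratio minimum peak observed/envelope ratio for an
#'   excursion to count as a demographic deviation.
#' @param brackets c(old, young) analysis window in cal BP.
#' @param edge_margin years next to the young bracket excluded from
#'   classification (calibration edge effects).
#' @param max_error laboratory-error cap in 14C yr.
#' @param growth_frac,pause_len,min_total_growth pulse-detection settings
#'   (see [detect_pulses()]).
#' @return list with `regions` (one row per recovered region: label,
#'   pulse, N, p, coverage, boom onset, predicted and true regime),
#'   `accuracy` (fraction correct; unclassifiable regions count as
#'   wrong), `stagger_ok` (are regime-2 boom onsets ordered with ring
#'   index), `pulses`, `partition`.
#' @export
regime_report <- function(world, n_sim = 500L, seed, h = 200,
                          alpha = 0.05, sustained_frac = 0.4,
                          excess_ratio = 1.25,
                          brackets = c(12000, 5000), edge_margin = 300,
                          max_error = 150, growth_frac = 0.05,
                          pause_len = 2L, min_total_growth = 0.15) {
  stopifnot(inherits(world, "synthetic_world"))
  if (missing(seed)) stop("regime_report requires a seed")
  curve <- world$curve
  d <- world$dates[world$dates$error <= max_error, , drop = FALSE]
  d$mode_age <- .cal_modes_c(d$cra, d$error, curve$mu, curve$sigma,
                             as.numeric(curve$grid))
  d <- d[!is.na(d$mode_age) & d$mode_age <= brackets[1L] &
           d$mode_age >= brackets[2L], , drop = FALSE]

  hs <- hull_series(d, range = c(brackets[1L], 4000))
  pulses <- detect_pulses(hs, growth_frac = growth_frac,
                          pause_len = pause_len,
                          min_total_growth = min_total_growth)
  if (!nrow(pulses)) stop("no dispersal pulses detected")
  part <- region_polygons(hs, pulses)
  d$region <- assign_regions(d, part)

  yb <- brackets[2L] + edge_margin
  rows <- list()
  onsets <- c()
  for (r in part$regions) {
    dr <- d[d$region == r$label, , drop = FALSE]
    neolith <- if (r$pulse > 0L) r$start else NULL
    res <- tryCatch(
      mcspd_test(dr, curve, window = brackets, neolithization = neolith,
                 h = h, n_sim = n_sim, seed = seed + r$pulse),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = r$label, pulse = r$pulse, n_bins = NA_integer_,
        p = NA_real_, coverage = NA_real_, boom_onset = NA_real_,
        predicted = NA_integer_, note = conditionMessage(res))
      next
    }
    cls <- classify_regime(res, young = yb, alpha = alpha,
                           sustained_frac = sustained_frac,
                           excess_ratio = excess_ratio,
                           is_origin = r$pulse == 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      label = r$label, pulse = r$pulse, n_bins = res$n_bins, p = res$p,
      coverage = cls$coverage, boom_onset = cls$onset,
      predicted = cls$regime, note = "")
  }
  regions <- do.call(rbind, rows)
  truth <- world$truth$rings
  regions$truth <- truth$regime[match(regions$pulse, truth$ring)]
  regions$correct <- !is.na(regions$predicted) &
    regions$predicted == regions$truth
  # staggering: regime-2 rings must boom in ring order (onsets get younger)
  r2 <- regions[!is.na(regions$truth) & regions$truth == 2L &
                  !is.na(regions$boom_onset), , drop = FALSE]
  r2 <- r2[order(r2$pulse), , drop = FALSE]
  stagger_ok <- nrow(r2) < 2L || !is.unsorted(rev(r2$boom_onset))
  list(regions = regions,
       accuracy = mean(regions$correct),
       stagger_ok = stagger_ok,
       pulses = pulses, partition = part)
}

#' Classify a regional MCSPD result into a demographic regime
#'
#' @param res an `mcspd_test`.
#' @param young young limit (cal BP) of the classification window.
#' @param alpha significance level.
#' @param sustained_frac coverage threshold separating regime 1 from 2.
#' @param excess_ratio minimum peak observed/envelope ratio for an
#'   excursion to count as a demographic deviation rather than a
#'   small-amplitude fluctuation of a well-sampled record.
#' @param is_origin is this the origin region? A substantial deviation at
#'   the innovation centre is a trend change by construction (regime 1),
#'   since no travelling front ever passes through the origin.
#' @return list with `regime` (1, 2 or 3), `coverage` (fraction of the
#'   post-arrival window spent above the envelope), `onset` (cal BP of
#'   the oldest above-excursion, NA if none) and `peak_ratio`.
#' @export
classify_regime <- function(res, young, alpha = 0.05,
                            sustained_frac = 0.4, excess_ratio = 1.25,
                            is_origin = FALSE) {
  stopifnot(inherits(res, "mcspd_test"))
  old <- res$neolithization
  sig <- res$sig_regions
  ab <- sig[sig$direction == "above", , drop = FALSE]
  g <- res$envelope$grid
  win <- g <= old & g >= young
  hi <- res$envelope$hi
  ratio <- ifelse(hi > 0, res$observed$density / hi, 0)
  peak <- if (any(win)) max(ratio[win]) else 0
  if (nrow(ab)) {   # clip excursions to the post-arrival window
    s <- pmin(ab$start, old); e <- pmax(ab$end, young)
    keep <- s > e
    cov <- sum((s - e)[keep]) / (old - young)
    onset <- if (any(keep)) max(s[keep]) else NA_real_
  } else {
    cov <- 0; onset <- NA_real_
  }
  regime <- if (res$p < alpha && cov > 0 && peak >= excess_ratio) {
    if (is_origin || cov >= sustained_frac) 1L else 2L
  } else 3L
  list(regime = regime, coverage = cov, onset = onset, peak_ratio = peak)
}
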