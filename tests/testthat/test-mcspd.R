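# A compact regional date table: Mesolithic background plus a Neolithic
# phase, all singleton sites.
region_dates <- function(seed, n_meso = 60, n_neo = 80, r = 3e-4,
                         neolith = 7500, curve = toy_curve()) {
  set.seed(seed)
  t_m <- neofront:::draw_exponential_ages(n_meso, r, neolith, 11500)
  t_n <- neofront:::draw_exponential_ages(n_neo, r, 5200, neolith)
  m <- uncalibrate(c(t_m, t_n), curve, 40, seed = seed + 1)
  d <- singleton_dates(m$cra, m$error)
  d$period <- rep(c("Mesolithic", "Neolithic"), c(n_meso, n_neo))
  d
}

test_that("the null model uses Mesolithic dates only", {
  crv <- toy_curve()
  d <- region_dates(1)
  nm <- fit_null(d, crv, neolithization = 7500)
  no_neo <- fit_null(d[d$period == "Mesolithic", ], crv,
                     neolithization = 7500)
  expect_equal(nm$fit$rate, no_neo$fit$rate, tolerance = 1e-12)
  expect_equal(nm$n_bins, no_neo$n_bins)
  # a region without foragers cannot anchor a null
  err <- tryCatch(fit_null(d[d$period == "Neolithic", ], crv, 7500),
                  error = function(e) e)
  expect_s3_class(err, "insufficient_data")
  err2 <- tryCatch(fit_null(d[c(1:4, 100:120), ], crv, 7500),
                   error = function(e) e)
  expect_s3_class(err2, "insufficient_data")
  expect_lt(err2$n_bins, 10)
})

test_that("the Mesolithic growth rate is recovered within its error", {
  crv <- toy_curve()
  ok <- 0L
  for (i in 1:10) {
    set.seed(700 + i)
    ages <- neofront:::draw_exponential_ages(250, 3e-4, 7000, 11800)
    m <- uncalibrate(ages, crv, 40, seed = 800 + i)
    d <- singleton_dates(m$cra, m$error, period = "Mesolithic")
    s <- compute_spd(d, crv, window = c(11800, 7000), keep_bins = TRUE)
    fit <- fit_exponential(s, window = c(11500, 7300), n_boot = 200,
                           seed = 900 + i)
    if (abs(fit$rate - 3e-4) <= 2 * fit$se) ok <- ok + 1L
  }
  expect_gte(ok, 8)
})

test_that("ensembles are reproducible and flat under a zero-rate null", {
  crv <- toy_curve()
  fit <- structure(list(rate = 0, rate_pct = 0, se = NA, C = 1,
                        window = c(10000, 6000), n_boot = 0,
                        corrected = FALSE), class = "growth_fit")
  e1 <- simulate_ensemble(fit, 100, error_pool = c(20, 30), curve = crv,
                          window = c(10000, 6000), n_sim = 200, seed = 5)
  e2 <- simulate_ensemble(fit, 100, error_pool = c(20, 30), curve = crv,
                          window = c(10000, 6000), n_sim = 200, seed = 5)
  expect_identical(e1$sims, e2$sims)
  # mean SPD flat away from the window edges, within Monte-Carlo error
  m <- rowMeans(e1$sims)
  interior <- e1$grid > 6400 & e1$grid < 9600
  expect_lt(sd(m[interior]) / mean(m[interior]), 0.1)
  expect_error(simulate_ensemble(fit, 50, c(20), crv, c(10000, 6000),
                                 n_sim = 5),
               "seed")
})

test_that("the ensemble mean converges toward the null as n_sim grows", {
  crv <- toy_curve()
  fit <- structure(list(rate = 3e-4, C = 1), class = "growth_fit")
  ref <- simulate_ensemble(fit, 100, c(30, 50), crv, c(9500, 6500),
                           n_sim = 1500, seed = 60)
  target <- rowMeans(ref$sims)
  dev <- function(e) max(abs(rowMeans(e$sims) - target))
  e100 <- simulate_ensemble(fit, 100, c(30, 50), crv, c(9500, 6500),
                            n_sim = 100, seed = 61)
  e1000 <- simulate_ensemble(fit, 100, c(30, 50), crv, c(9500, 6500),
                             n_sim = 1000, seed = 62)
  expect_lt(dev(e1000), dev(e100))
})

test_that("envelope flags exactly the constructed excursions", {
  crv <- toy_curve()
  fit <- structure(list(rate = 3e-4, C = 1), class = "growth_fit")
  ens <- simulate_ensemble(fit, 100, c(30, 50), crv, c(10000, 6000),
                           n_sim = 400, seed = 70)
  grid <- ens$grid
  base <- rowMeans(ens$sims)
  obs <- structure(list(grid = grid, density = base, n_bins = 100,
                        scale = "raw", window = c(10000, 6000),
                        corrected = FALSE), class = "spd")
  env0 <- mc_envelope(obs, ens)
  expect_equal(nrow(env0$sig_regions), 0)
  # push a 500-yr block 1.5x above the upper envelope
  block <- grid <= 8500 & grid >= 8000
  obs2 <- obs
  obs2$density[block] <- 1.5 * env0$hi[block]
  env2 <- mc_envelope(obs2, ens)
  above <- env2$sig_regions[env2$sig_regions$direction == "above", ]
  expect_equal(nrow(above), 1)
  expect_lte(abs(above$start - 8500), 25)  # mass matching shifts slightly
  expect_lte(abs(above$end - 8000), 25)
  # grid mismatch is an error
  obs3 <- obs; obs3$grid <- obs3$grid + 1
  expect_error(mc_envelope(obs3, ens), "grid")
})

test_that("the global p-value is 1 for the ensemble mean and never 0", {
  crv <- toy_curve()
  fit <- structure(list(rate = 3e-4, C = 1), class = "growth_fit")
  ens <- simulate_ensemble(fit, 80, c(30, 50), crv, c(9500, 6500),
                           n_sim = 200, seed = 80)
  obs <- structure(list(grid = ens$grid, density = rowMeans(ens$sims),
                        n_bins = 80, scale = "raw",
                        window = c(9500, 6500), corrected = FALSE),
                   class = "spd")
  gp <- global_pvalue(obs, ens)
  expect_equal(gp$p, 1)
  expect_gte(gp$p, 1 / 201)
})

test_that("held-out null p-values are uniform", {
  nc <- mcspd_null_calibration(n_rep = 60, n_sim = 200, n_bins = 60,
                               seed = 314)
  # rank p-values are discrete, so exact ties are expected; the KS
  # statistic itself is still the right uniformity summary here
  ks <- suppressWarnings(stats::ks.test(nc$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("enlarging an excursion never increases the global p-value", {
  crv <- toy_curve()
  fit <- structure(list(rate = 3e-4, C = 1), class = "growth_fit")
  ens <- simulate_ensemble(fit, 100, c(30, 50), crv, c(10000, 6000),
                           n_sim = 300, seed = 90)
  base <- rowMeans(ens$sims)
  block <- ens$grid <= 8500 & ens$grid >= 8000
  ps <- vapply(c(1, 1.3, 1.8, 2.5, 4), function(f) {
    d <- base; d[block] <- f * d[block]
    obs <- structure(list(grid = ens$grid, density = d, n_bins = 100,
                          scale = "raw", window = c(10000, 6000),
                          corrected = FALSE), class = "spd")
    global_pvalue(obs, ens)$p
  }, 0.0)
  expect_true(all(diff(ps) <= 0))
})

test_that("the end-to-end regional test is seeded and reproducible", {
  crv <- toy_curve()
  d <- region_dates(5)
  r1 <- mcspd_test(d, crv, window = c(11500, 5200), n_sim = 150, seed = 44)
  r2 <- mcspd_test(d, crv, window = c(11500, 5200), n_sim = 150, seed = 44)
  expect_identical(r1$p, r2$p)
  expect_identical(r1$envelope, r2$envelope)
  expect_equal(r1$n_bins, attr(bin_dates(d), "n_bins"))
  # neolithization defaults to the oldest Neolithic mode
  modes <- vapply(which(d$period == "Neolithic"), function(i)
    calibrate(d$cra[i], d$error[i], crv)$mode, 0)
  expect_equal(r1$neolithization, max(modes))
})

test_that("results serialise to CSV plus JSON sidecar", {
  crv <- toy_curve()
  d <- region_dates(6)
  res <- mcspd_test(d, crv, window = c(11500, 5200), n_sim = 100, seed = 3)
  stem <- file.path(withr::local_tempdir(), "regionA")
  write_mcspd_result(res, stem)
  tab <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(tab), length(res$envelope$grid))
  expect_true(all(c("observed", "envelope_lo", "envelope_hi",
                    "above", "below") %in% names(tab)))
  side <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(side$n_bins, res$n_bins)
  expect_equal(side$global_p, res$p)
  expect_equal(side$seed, 3)
})
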