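test_that("site-phase binning chains dates within h radiocarbon years", {
  d <- singleton_dates(c(6000, 6100), 30)
  d$site <- "A"
  expect_equal(attr(bin_dates(d, h = 200), "n_bins"), 1)
  expect_equal(attr(bin_dates(d, h = 50), "n_bins"), 2)
  # degenerate widths
  d2 <- singleton_dates(c(5000, 5000, 7000, 9000), 30)
  d2$site <- "B"
  expect_equal(attr(bin_dates(d2, h = 0), "n_bins"), 3)  # exact ties chain
  expect_equal(attr(bin_dates(d2, h = Inf), "n_bins"), 1)
})

test_that("bin counts match a single-linkage clustering oracle", {
  set.seed(31)
  d <- data.frame(site = sample(LETTERS[1:10], 100, TRUE),
                  cra = runif(100, 4000, 9000))
  h <- 150
  oracle <- sum(vapply(split(d$cra, d$site), function(x) {
    if (length(x) == 1) return(1L)
    cl <- stats::cutree(stats::hclust(stats::dist(x), method = "single"),
                        h = h)
    length(unique(cl))
  }, 0L))
  expect_equal(attr(bin_dates(d, h = h), "n_bins"), oracle)
})

test_that("the SPD of a single date is its calibrated density", {
  crv <- toy_curve()
  d <- singleton_dates(7000, 40)
  s <- compute_spd(d, crv, window = c(9000, 5000))
  cd <- calibrate(7000, 40, crv)
  expect_equal(s$n_bins, 1)
  idx <- match(cd$grid, s$grid)
  expect_equal(s$density[idx], cd$mass, tolerance = 1e-12)
  expect_equal(sum(s$density), 1, tolerance = 1e-4)
})

test_that("a bin contributes the mean of its member densities", {
  crv <- toy_curve()
  d <- singleton_dates(c(7000, 7080), 40)
  d$site <- "A"
  s <- compute_spd(bin_dates(d, h = 200), crv, window = c(9000, 5000))
  expect_equal(s$n_bins, 1)
  expect_equal(sum(s$density), 1, tolerance = 1e-4)
  c1 <- calibrate(7000, 40, crv); c2 <- calibrate(7080, 40, crv)
  at <- 7040 - s$grid[1] + 1
  expect_equal(s$density[at],
               (c1$mass[7040 - c1$grid[1] + 1] +
                  c2$mass[7040 - c2$grid[1] + 1]) / 2,
               tolerance = 1e-12)
})

test_that("raw SPD mass equals the number of bins", {
  crv <- toy_curve()
  set.seed(8)
  for (k in c(3, 17)) {
    d <- singleton_dates(runif(k, 6500, 7500), runif(k, 20, 80))
    s <- compute_spd(d, crv, window = c(9500, 4500))
    expect_equal(s$n_bins, k)
    expect_equal(sum(s$density), k, tolerance = 1e-4)
  }
})

test_that("rescaling normalises per bin or to unit area and is idempotent", {
  crv <- toy_curve()
  d <- singleton_dates(runif(5, 6500, 7500), 40)
  s <- compute_spd(d, crv, window = c(9000, 5000))
  pb <- rescale_spd(s, "per-bin")
  expect_equal(sum(pb$density), 1, tolerance = 1e-4)
  ua <- rescale_spd(s, "unit-area")
  expect_equal(sum(ua$density), 1, tolerance = 1e-12)
  expect_identical(rescale_spd(pb, "per-bin"), pb)
  expect_error(rescale_spd(pb, "unit-area"), "raw")
})

test_that("taphonomic correction follows the survival power law", {
  surv <- neofront:::taphonomic_survival
  expect_equal(surv(12000) / surv(4000),
               (14176.4 / 6176.4)^(-1.3925309), tolerance = 1e-12)
  crv <- identity_curve()
  s <- structure(list(grid = 4000:12000,
                      density = rep(1 / 8001, 8001), n_bins = 1,
                      scale = "raw", window = c(12000, 4000),
                      corrected = FALSE, bin_densities = NULL),
                 class = "spd")
  cs <- correct_taphonomy(s)
  # total mass preserved; loss correction shifts mass toward older years
  expect_equal(sum(cs$density), sum(s$density), tolerance = 1e-12)
  expect_true(all(diff(cs$density) > 0))   # grid ascends toward older
  expect_true(cs$corrected)
  # flat input: corrected ratio equals the inverse survival ratio
  i1 <- match(12000, cs$grid); i2 <- match(4000, cs$grid)
  expect_equal(cs$density[i1] / cs$density[i2],
               surv(4000) / surv(12000), tolerance = 1e-12)
  expect_identical(correct_taphonomy(cs), cs)
})

test_that("an exact exponential SPD is recovered to printed precision", {
  grid <- 5000:10000
  r <- 4.38e-4
  s <- structure(list(grid = grid, density = 5 * exp(-r * grid),
                      n_bins = 10, scale = "raw",
                      window = c(10000, 5000), corrected = FALSE,
                      bin_densities = NULL),
                 class = "spd")
  fit <- fit_exponential(s, n_boot = 0)
  expect_equal(fit$rate_pct, 0.0438, tolerance = 1e-5)
  flat <- s; flat$density <- rep(1, length(grid))
  f0 <- fit_exponential(flat, n_boot = 0)
  expect_lt(abs(f0$rate), 1e-8)
})

test_that("growth rates are recovered from noisy calibrated data", {
  crv <- toy_curve()
  r_true <- 4e-4
  ok <- 0L
  for (i in 1:10) {
    set.seed(400 + i)
    ages <- neofront:::draw_exponential_ages(500, r_true, 5500, 10500)
    m <- uncalibrate(ages, crv, 40, seed = 500 + i)
    d <- singleton_dates(m$cra, m$error)
    s <- compute_spd(d, crv, window = c(10500, 5500), keep_bins = TRUE)
    fit <- fit_exponential(s, window = c(10200, 5800), n_boot = 200,
                           seed = 600 + i)
    if (abs(fit$rate - r_true) <= 2 * fit$se) ok <- ok + 1L
  }
  expect_gte(ok, 8)
})
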