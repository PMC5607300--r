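test_that("a fixed triangle yields the same hull and area at every step", {
  pts <- data.frame(lon = c(10, 12, 11), lat = c(44, 44, 46),
                    mode_age = c(11900, 11800, 11950))
  ctr <- c(11, 44.7)
  hs <- hull_series(pts, range = c(11800, 11000), center = ctr)
  expect_true(all(diff(hs$area) == 0))
  a_geo <- geosphere::areaPolygon(cbind(pts$lon, pts$lat)) / 1e6
  expect_equal(hs$area[1], a_geo, tolerance = 0.01)
  # an interior point changes nothing
  pts2 <- rbind(pts, data.frame(lon = 11, lat = 44.5, mode_age = 11850))
  hs2 <- hull_series(pts2, range = c(11800, 11000), center = ctr)
  expect_equal(hs2$area, hs$area, tolerance = 1e-9)
})

test_that("hulls are nested with non-decreasing areas on random inputs", {
  set.seed(9)
  for (rep in 1:5) {
    pts <- data.frame(lon = runif(120, 0, 30), lat = runif(120, 35, 55),
                      mode_age = sample(4000:12000, 120, TRUE))
    hs <- hull_series(pts)
    expect_true(all(diff(hs$area) >= -1e-9))
    # nesting: every vertex of the previous hull lies in the next hull
    for (k in 2:length(hs$tau)) {
      h0 <- hs$hulls[[k - 1]]; h1 <- hs$hulls[[k]]
      if (is.null(h0) || is.null(h1)) next
      st <- neofront:::points_in_polygon(h0, h1, tol = 1e-6)
      expect_true(all(st > 0L))
    }
  }
})

test_that("a radial front produces hull areas near the disc area", {
  set.seed(5)
  n <- 2000
  v <- 0.7                       # km/yr; keeps radii well under Earth scale
  age <- sample(seq(8200, 11800, by = 100), n, replace = TRUE)
  r_km <- v * (12000 - age)
  brg <- runif(n, 0, 360)
  ll <- geosphere::destPoint(c(20, 45), brg, r_km * 1000)
  pts <- data.frame(lon = ll[, 1], lat = ll[, 2], mode_age = age)
  hs <- hull_series(pts, range = c(12000, 8200))
  late <- which(hs$n >= 200)
  expected <- pi * (v * (12000 - hs$tau[late]))^2
  expect_true(all(abs(hs$area[late] / expected - 1) < 0.05))
})

make_series <- function(area) {
  tau <- seq(12000, 12000 - 100 * (length(area) - 1), by = -100)
  structure(list(tau = tau, area = area, n = rep(10L, length(area)),
                 hulls = vector("list", length(area)),
                 center = c(0, 0), step = 100),
            class = "hull_series")
}

test_that("a constant-area series contains no pulses", {
  hs <- make_series(rep(500, 30))
  expect_equal(nrow(detect_pulses(hs)), 0)
})

test_that("a six-jump staircase yields exactly six pulses at the jumps", {
  # growth appears at the step after each start boundary; each jump is a
  # two-step ramp followed by at least two flat steps
  area <- c(100, 100, 100)
  jumps <- list()
  for (j in 1:6) {
    a0 <- area[length(area)]
    area <- c(area, a0 * 1.4, a0 * 1.9, a0 * 1.9, a0 * 1.9, a0 * 1.9)
  }
  hs <- make_series(area)
  p <- detect_pulses(hs)
  expect_equal(nrow(p), 6)
  starts_expected <- hs$tau[c(3, 8, 13, 18, 23, 28)]
  ends_expected <- hs$tau[c(5, 10, 15, 20, 25, 30)]
  expect_equal(p$start, starts_expected)
  expect_equal(p$end, ends_expected)
})

test_that("pulse detection ignores establishment and prepended flats", {
  area <- c(0, 0, 50, 400, 420, 420, 420, 420, 800, 900, 900, 900, 900)
  hs <- make_series(area)
  p <- detect_pulses(hs)
  expect_equal(nrow(p), 1)               # only the post-pause episode
  expect_equal(p$start, hs$tau[8])
  # prepending constant steps does not change the result
  hs2 <- make_series(c(rep(0, 5), area))
  p2 <- detect_pulses(hs2)
  expect_equal(nrow(p2), 1)
  expect_equal(p2$growth, p$growth)
  # idempotence: same input, same output
  expect_identical(detect_pulses(hs), p)
})

test_that("small episodes below the total-growth floor are discarded", {
  area <- c(100, 100, 100, 108, 108, 108, 108, 300, 300, 300)
  p <- detect_pulses(make_series(area))
  expect_equal(nrow(p), 1)
  expect_equal(p$area_end, 300)
})

square_series <- function() {
  # two concentric squares as hulls: inner at the first boundaries, outer
  # after a jump, with long flat stretches so detection is clean
  inner <- cbind(c(-100, 100, 100, -100), c(-100, -100, 100, 100))
  outer <- inner * 2
  tau <- seq(12000, 9000, by = -100)
  hulls <- vector("list", length(tau))
  area <- numeric(length(tau))
  for (k in seq_along(tau)) {
    h <- if (tau[k] > 10500) inner else outer
    hulls[[k]] <- h; area[k] <- polygon_area(h)
  }
  structure(list(tau = tau, area = area, n = rep(20L, length(tau)),
                 hulls = hulls, center = c(20, 45), step = 100),
            class = "hull_series")
}

test_that("concentric hulls produce an origin and a ring with exact areas", {
  hs <- square_series()
  p <- detect_pulses(hs)
  expect_equal(nrow(p), 1)
  part <- region_polygons(hs, p)
  expect_equal(length(part$regions), 2)
  areas <- vapply(part$regions, function(r) r$area, 0)
  expect_equal(areas, c(200^2, 400^2 - 200^2))
  expect_equal(sum(areas), part$final_area, tolerance = 1e-9)
})

test_that("split lines bisect regions and preserve the partition", {
  hs <- square_series()
  part <- region_polygons(hs, detect_pulses(hs))
  # vertical midline through the projection centre
  line <- laea_unproject(rbind(c(0, -500), c(0, 500)), part$center)
  split <- apply_splits(part, list(list(region = "R0", line = line)))
  labs <- vapply(split$regions, function(r) r$label, "")
  expect_setequal(labs, c("R0a", "R0b", "R1"))
  halves <- split$regions[labs != "R1"]
  expect_equal(halves[[1]]$area, halves[[2]]$area, tolerance = 1e-6)
  expect_equal(sum(vapply(split$regions, function(r) r$area, 0)),
               part$final_area, tolerance = 1e-6)
  # a line that misses the region entirely is an error
  far <- laea_unproject(rbind(c(5000, -500), c(5000, 500)), part$center)
  expect_error(apply_splits(part, list(list(region = "R1", line = far))),
               "cross")
  expect_error(apply_splits(part, list(list(region = "nope", line = line))),
               "unknown region")
})

test_that("dates are assigned to regions with the earlier-pulse tie-break", {
  hs <- square_series()
  part <- region_polygons(hs, detect_pulses(hs))
  pts_xy <- rbind(c(0, 0),      # origin interior
                  c(150, 0),    # ring interior
                  c(100, 0),    # shared boundary -> origin (earlier pulse)
                  c(500, 500))  # outside everything
  ll <- laea_unproject(pts_xy, part$center)
  lab <- assign_regions(data.frame(lon = ll[, 1], lat = ll[, 2]), part)
  expect_equal(lab, c("R0", "R1", "R0", "unassigned"))
})

test_that("partition survives a GeoJSON round trip", {
  hs <- square_series()
  part <- region_polygons(hs, detect_pulses(hs))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_partition_geojson(part, f)
  back <- read_partition_geojson(f)
  expect_equal(length(back$regions), length(part$regions))
  expect_equal(vapply(back$regions, function(r) r$area, 0),
               vapply(part$regions, function(r) r$area, 0),
               tolerance = 1e-6)
  expect_equal(back$final_area, part$final_area, tolerance = 1e-6)
})
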