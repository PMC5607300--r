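#' Time-stratified convex-hull series of an expanding settlement front
#'
#' For each 100-year boundary tau in the study range, builds the smallest
#' convex polygon containing every point whose calibrated mode age is at
#' least tau (i.e. every site dated at or before that moment). Because the
#' point sets are cumulative as tau decreases, the hulls are nested and
#' their areas non-decreasing: the series traces the area ever occupied by
#' the dispersing population. Areas are computed on a Lambert azimuthal
#' equal-area plane centred on the point cloud.
#'
#' @param points data.frame with columns `lon`, `lat`, `mode_age` (cal BP)
#'   and optionally `period`; when a `period` column is present only rows
#'   with `period == "Neolithic"` are used.
#' @param step interval width in years (default 100).
#' @param range c(oldest, youngest) cal BP boundaries, default
#'   c(12000, 4000).
#' @param center optional projection centre c(lon, lat); defaults to the
#'   mean of the points used.
#' @return Object of class `hull_series`: list with `tau` (descending
#'   boundaries), `area` (km^2 per boundary), `n` (points per boundary),
#'   `hulls` (CCW vertex matrices in projected km, NULL where fewer than
#'   three non-collinear points exist) and `center`.
#' @export
hull_series <- function(points, step = 100, range = c(12000, 4000),
                        center = NULL) {
  stopifnot(all(c("lon", "lat", "mode_age") %in% names(points)))
  if ("period" %in% names(points))
    points <- points[points$period == "Neolithic", , drop = FALSE]
  # points older than the first boundary belong to every cumulative hull;
  # points younger than the last boundary never enter one
  points <- points[points$mode_age >= range[2L], , drop = FALSE]
  if (nrow(points) < 3L)
    stop("need at least 3 points within the study range")
  if (is.null(center))
    center <- c(mean(points$lon), mean(points$lat))
  xy <- laea_project(cbind(points$lon, points$lat), center)
  tau <- seq(range[1L], range[2L], by = -abs(step))
  hulls <- vector("list", length(tau))
  area <- numeric(length(tau)); n <- integer(length(tau))
  for (k in seq_along(tau)) {
    sel <- points$mode_age >= tau[k]
    n[k] <- sum(sel)
    h <- if (n[k] >= 3L) convex_hull(xy[sel, , drop = FALSE]) else NULL
    hulls[[k]] <- h
    area[k] <- polygon_area(h)
  }
  structure(list(tau = tau, area = area, n = n, hulls = hulls,
                 center = center, step = abs(step)),
            class = "hull_series")
}

#' Detect dispersal pulses from hull-area dynamics
#'
#' A pulse is an episode of rapid areal expansion. Scanning the hull-area
#' series forward in time, a pulse starts at the first boundary whose
#' fractional area increase over the previous boundary exceeds
#' `growth_frac`, provided at least `pause_len` consecutive sub-threshold
#' steps (a pause) precede it; it ends at the last super-threshold boundary
#' before growth stays below threshold for `pause_len` steps. Growth while
#' the series is still establishing itself (before the first pause,
#' including the initial appearance of the founding area) is not scored as
#' a pulse. Detected episodes whose total relative growth is below
#' `min_total_growth` are discarded as noise from single straggler sites.
#'
#' A growth observed at boundary tau means the front moved during the
#' interval (tau + step, tau]; the reported pulse `start` is therefore the
#' older boundary tau + step — the moment the frontier is first trespassed
#' — while `end` is the younger boundary of the last growing interval, the
#' moment growth stalls.
#'
#' @param series a [hull_series].
#' @param growth_frac per-step fractional growth threshold (default 0.05).
#' @param pause_len number of consecutive sub-threshold steps defining a
#'   pause (default 2).
#' @param min_total_growth minimum total relative area growth
#'   (A_end/A_start - 1) for an episode to count as a pulse (default 0.15).
#' @return data.frame with one row per pulse: `start`, `end` (cal BP
#'   boundaries, start > end), `area_start`, `area_end`, `growth` (total
#'   relative growth). Zero rows when the series never pulses.
#' @export
detect_pulses <- function(series, growth_frac = 0.05, pause_len = 2L,
                          min_total_growth = 0.15) {
  stopifnot(inherits(series, "hull_series"))
  tau <- series$tau; A <- series$area
  if (length(tau) < 3L) stop("hull series too short for pulse detection")
  growth <- rep(0, length(tau))
  for (k in 2:length(tau)) {
    growth[k] <- if (A[k - 1L] > 0) (A[k] - A[k - 1L]) / A[k - 1L]
                 else if (A[k] > 0) Inf else 0
  }
  pulses <- list()
  pause <- 0L; in_pulse <- FALSE
  start_k <- NA_integer_; last_above <- NA_integer_; below <- 0L
  close_pulse <- function() {
    gr <- A[last_above] / A[start_k - 1L] - 1
    if (is.finite(gr) && gr >= min_total_growth)
      pulses[[length(pulses) + 1L]] <<-
        data.frame(start = tau[start_k - 1L], end = tau[last_above],
                   area_start = A[start_k - 1L], area_end = A[last_above],
                   growth = gr)
  }
  for (k in 2:length(tau)) {
    scoreable <- A[k - 1L] > 0          # growth from nothing is establishment
    above <- scoreable && growth[k] > growth_frac
    if (in_pulse) {
      if (above) {
        last_above <- k; below <- 0L
      } else {
        below <- below + 1L
        if (below >= pause_len) {
          close_pulse()
          in_pulse <- FALSE
          pause <- below
        }
      }
    } else if (above && pause >= pause_len) {
      in_pulse <- TRUE; start_k <- k; last_above <- k; below <- 0L
    } else if (!above && scoreable) {
      pause <- pause + 1L
    } else if (!scoreable) {
      pause <- 0L
    }
  }
  if (in_pulse) close_pulse()
  if (!length(pulses))
    return(data.frame(start = numeric(0), end = numeric(0),
                      area_start = numeric(0), area_end = numeric(0),
                      growth = numeric(0)))
  do.call(rbind, pulses)
}

#' Derive the dispersal-defined region partition
#'
#' Region 0 is the founding hull (the hull at the first pulse's start
#' boundary); region k is the ring gained during pulse k: the hull at the
#' end of pulse k minus the hull at the end of pulse k-1. Because the hulls
#' are nested, each ring is an outer convex polygon with (at most) one
#' convex hole. Rings whose area falls below `min_area` are dropped as
#' degenerate slivers, with a warning.
#'
#' @param series a [hull_series].
#' @param pulses data.frame from [detect_pulses()]; at least one row.
#' @param min_area sliver tolerance in km^2 (default 1).
#' @return Object of class `region_partition`: list with `regions` (each a
#'   list with `label`, `outer`, `hole` vertex matrices in projected km,
#'   `pulse`, `start`, `end`, `area`), `center` (projection centre) and
#'   `final_area`.
#' @export
region_polygons <- function(series, pulses, min_area = 1) {
  stopifnot(inherits(series, "hull_series"), nrow(pulses) >= 1L)
  hull_at <- function(t) {
    k <- match(t, series$tau)
    if (is.na(k)) stop("boundary ", t, " not in hull series")
    series$hulls[[k]]
  }
  np <- nrow(pulses)
  regions <- list()
  origin <- hull_at(pulses$start[1L])
  if (!is.null(origin) && polygon_area(origin) >= min_area) {
    regions[[1L]] <- list(label = "R0", outer = origin, hole = NULL,
                          pulse = 0L, start = NA_real_,
                          end = pulses$start[1L],
                          area = polygon_area(origin))
  } else {
    warning("founding hull empty or below sliver tolerance; ",
            "origin region dropped")
  }
  prev <- origin
  for (k in seq_len(np)) {
    outer <- hull_at(pulses$end[k])
    a <- polygon_area(outer) - polygon_area(prev)
    if (is.null(outer) || a < min_area) {
      warning("ring for pulse ", k, " is degenerate; region dropped")
    } else {
      regions[[length(regions) + 1L]] <-
        list(label = paste0("R", k), outer = outer, hole = prev,
             pulse = k, start = pulses$start[k], end = pulses$end[k],
             area = a)
    }
    prev <- outer
  }
  if (!length(regions)) stop("no non-degenerate regions")
  structure(list(regions = regions, center = series$center,
                 final_area = polygon_area(prev)),
            class = "region_partition")
}

#' Split regions along cultural border lines
#'
#' Bisects target regions by the infinite line through the first and last
#' vertex of a supplied polyline (in lon/lat), assigning a label suffix per
#' side. Both the outer polygon and any hole are clipped by the two
#' half-planes, so the partition invariants (disjoint interiors, union
#' preserved) are maintained. A line that does not pass through the target
#' region's interior is an error.
#'
#' @param partition a `region_partition`.
#' @param splits list of splits, each a list with `region` (label of the
#'   region to split), `line` (two-column lon/lat matrix; first and last
#'   point define the cutting line) and optionally `labels` (two suffixes,
#'   default c("a", "b")).
#' @param min_area sliver tolerance in km^2.
#' @return a new `region_partition` with the split regions replaced.
#' @export
apply_splits <- function(partition, splits, min_area = 1) {
  stopifnot(inherits(partition, "region_partition"))
  regions <- partition$regions
  for (sp in splits) {
    idx <- which(vapply(regions, function(r) r$label, "") == sp$region)
    if (!length(idx))
      stop("split targets unknown region '", sp$region, "'")
    r <- regions[[idx]]
    ln <- laea_project(sp$line[c(1L, nrow(sp$line)), , drop = FALSE],
                       partition$center)
    d <- ln[2L, ] - ln[1L, ]
    if (sum(d^2) == 0) stop("degenerate split line for region '",
                            sp$region, "'")
    a <- -d[2L]; b <- d[1L]; cc <- -(a * ln[1L, 1L] + b * ln[1L, 2L])
    labs <- if (!is.null(sp$labels)) sp$labels else c("a", "b")
    halves <- list()
    for (side in 1:2) {
      s <- if (side == 1L) 1 else -1
      outer <- clip_halfplane(r$outer, s * a, s * b, s * cc)
      hole <- clip_halfplane(r$hole, s * a, s * b, s * cc)
      area <- polygon_area(outer) - polygon_area(hole)
      if (!is.null(outer) && area >= min_area)
        halves[[length(halves) + 1L]] <-
          list(label = paste0(r$label, labs[side]), outer = outer,
               hole = hole, pulse = r$pulse, start = r$start, end = r$end,
               area = area)
    }
    if (length(halves) < 2L)
      stop("split line does not cross region '", sp$region, "'")
    regions <- append(regions[-idx], halves, after = idx - 1L)
  }
  partition$regions <- regions
  partition
}

#' Assign dates to partition regions
#'
#' Point-in-polygon assignment of each date to the region containing it.
#' Points on a shared boundary are assigned to the earlier-pulse region
#' (the front defines first arrival); points in no region are labelled
#' `"unassigned"`.
#'
#' @param dates data.frame with `lon` and `lat` columns.
#' @param partition a `region_partition`.
#' @param tol boundary tolerance in km.
#' @return character vector of region labels, one per row of `dates`.
#' @export
assign_regions <- function(dates, partition, tol = 1e-6) {
  stopifnot(inherits(partition, "region_partition"))
  xy <- laea_project(cbind(dates$lon, dates$lat), partition$center)
  ord <- order(vapply(partition$regions, function(r) r$pulse, 0L),
               vapply(partition$regions, function(r) r$label, ""))
  lab <- rep("unassigned", nrow(xy))
  todo <- rep(TRUE, nrow(xy))
  for (r in partition$regions[ord]) {
    if (!any(todo)) break
    sub <- which(todo)
    st_out <- points_in_polygon(xy[sub, , drop = FALSE], r$outer, tol)
    hit <- st_out > 0L
    if (!is.null(r$hole) && any(hit)) {
      st_hole <- points_in_polygon(xy[sub[hit], , drop = FALSE], r$hole, tol)
      hit[hit] <- st_hole != 1L   # strict hole interior is excluded
    }
    lab[sub[hit]] <- r$label
    todo[sub[hit]] <- FALSE
  }
  lab
}

#' @export
print.hull_series <- function(x, ...) {
  cat("<hull_series> ", length(x$tau), " boundaries, ",
      x$tau[1L], "-", x$tau[length(x$tau)], " cal BP (step ", x$step,
      " yr); final area ", format(round(max(x$area))), " km^2\n", sep = "")
  invisible(x)
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> ", length(x$regions), " regions, total area ",
      format(round(x$final_area)), " km^2\n", sep = "")
  for (r in x$regions)
    cat(sprintf("  %-6s pulse %d  area %12.0f km^2\n",
                r$label, r$pulse, r$area))
  invisible(x)
}

#' Export a region partition to GeoJSON
#'
#' Writes one Feature per region (Polygon in WGS84 lon/lat, holes as inner
#' rings) with properties `label`, `pulse`, `pulse_start`, `pulse_end` and
#' `area_km2`; the projection centre is stored as a foreign member so the
#' partition can be read back with [read_partition_geojson()].
#'
#' @param partition a `region_partition`.
#' @param path output file.
#' @export
write_partition_geojson <- function(partition, path) {
  ring_ll <- function(poly) {
    ll <- laea_unproject(poly, partition$center)
    ll <- rbind(ll, ll[1L, , drop = FALSE])         # close the ring
    lapply(seq_len(nrow(ll)), function(i) c(ll[i, 1L], ll[i, 2L]))
  }
  feats <- lapply(partition$regions, function(r) {
    rings <- list(ring_ll(r$outer))
    if (!is.null(r$hole)) rings <- c(rings, list(rev(ring_ll(r$hole))))
    list(type = "Feature",
         properties = list(label = r$label, pulse = r$pulse,
                           pulse_start = r$start, pulse_end = r$end,
                           area_km2 = r$area),
         geometry = list(type = "Polygon", coordinates = rings))
  })
  obj <- list(type = "FeatureCollection",
              projection_center = partition$center,
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 10,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a region partition from GeoJSON written by [write_partition_geojson()]
#'
#' @param path GeoJSON file.
#' @return a `region_partition`.
#' @export
read_partition_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  center <- as.numeric(unlist(obj$projection_center))
  to_poly <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
    m <- m[-nrow(m), , drop = FALSE]                # drop closing vertex
    h <- laea_project(m, center)
    if (signed_area(h) < 0) h <- h[nrow(h):1L, , drop = FALSE]
    h
  }
  regions <- lapply(obj$features, function(f) {
    rings <- f$geometry$coordinates
    outer <- to_poly(rings[[1L]])
    hole <- if (length(rings) > 1L) to_poly(rings[[2L]]) else NULL
    pr <- f$properties
    list(label = pr$label, outer = outer, hole = hole,
         pulse = as.integer(pr$pulse),
         start = if (is.null(pr$pulse_start)) NA_real_
                 else as.numeric(pr$pulse_start),
         end = as.numeric(pr$pulse_end),
         area = polygon_area(outer) - polygon_area(hole))
  })
  final <- max(vapply(regions, function(r) polygon_area(r$outer), 0))
  structure(list(regions = regions, center = center, final_area = final),
            class = "region_partition")
}
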