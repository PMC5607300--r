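# Planar geometry on an equal-area projection.
#
# All front-tracking geometry runs in kilometres on a Lambert azimuthal
# equal-area (LAEA) plane centred on the point cloud, so polygon areas are
# areas on the sphere to very good approximation at continental scale.
# The shapes involved are convex hulls, ring differences of *nested* hulls
# and half-plane splits of those, so a handful of classic primitives
# (shoelace area, Sutherland-Hodgman half-plane clipping, even-odd
# point-in-polygon) covers everything; no general polygon-overlay engine
# is required.

EARTH_RADIUS_KM <- 6371.0088

#' Lambert azimuthal equal-area projection
#'
#' Projects lon/lat (degrees, WGS84) to planar kilometres on an equal-area
#' plane centred at `center`, and back.
#'
#' @param lonlat two-column matrix (lon, lat) in degrees.
#' @param center c(lon, lat) of the projection centre in degrees.
#' @return `laea_project`: two-column matrix (x, y) in km.
#' @export
laea_project <- function(lonlat, center) {
  lonlat <- matrix(as.numeric(lonlat), ncol = 2L)
  lam <- lonlat[, 1L] * pi / 180; phi <- lonlat[, 2L] * pi / 180
  lam0 <- center[1L] * pi / 180;  phi0 <- center[2L] * pi / 180
  dl <- lam - lam0
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  k <- sqrt(2 / pmax(denom, 1e-12))
  cbind(x = EARTH_RADIUS_KM * k * cos(phi) * sin(dl),
        y = EARTH_RADIUS_KM * k *
          (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl)))
}

#' @rdname laea_project
#' @param xy two-column matrix (x, y) in km.
#' @export
laea_unproject <- function(xy, center) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  lam0 <- center[1L] * pi / 180; phi0 <- center[2L] * pi / 180
  x <- xy[, 1L] / EARTH_RADIUS_KM; y <- xy[, 2L] / EARTH_RADIUS_KM
  rho <- sqrt(x^2 + y^2)
  cc <- 2 * asin(pmin(rho / 2, 1))
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(cc) * sin(phi0) + y * sin(cc) * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sin(cc),
                             rho * cos(phi0) * cos(cc) -
                               y * sin(phi0) * sin(cc)))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

# Signed shoelace area; positive for counter-clockwise vertex order.
signed_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3L) return(0)
  x <- poly[, 1L]; y <- poly[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (shoelace formula)
#'
#' @param poly two-column matrix of vertices (open ring) in km.
#' @return area in km^2 (0 for degenerate polygons).
#' @export
polygon_area <- function(poly) abs(signed_area(poly))

# Convex hull of planar points as a CCW-ordered open ring, or NULL when the
# points are too few or collinear to span an area.
convex_hull <- function(xy) {
  xy <- unique(matrix(as.numeric(xy), ncol = 2L))
  if (nrow(xy) < 3L) return(NULL)
  h <- xy[grDevices::chull(xy), , drop = FALSE]
  if (nrow(h) < 3L || polygon_area(h) <= 0) return(NULL)
  if (signed_area(h) < 0) h <- h[nrow(h):1L, , drop = FALSE]
  h
}

# Clip a convex polygon to the half-plane a*x + b*y + c >= 0
# (Sutherland-Hodgman against a single edge). Returns NULL if empty.
clip_halfplane <- function(poly, a, b, c) {
  if (is.null(poly)) return(NULL)
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2L)
  d <- a * poly[, 1L] + b * poly[, 2L] + c
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (d[i] >= 0) out <- rbind(out, poly[i, ])
    if ((d[i] > 0 && d[j] < 0) || (d[i] < 0 && d[j] > 0)) {
      t <- d[i] / (d[i] - d[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  if (nrow(out) < 3L || polygon_area(out) <= 0) return(NULL)
  out
}

# Point-in-polygon for a batch of points (even-odd rule with an explicit
# boundary band). Returns an integer per point: 0 outside, 1 strictly
# inside, 2 within `tol` of the boundary.
points_in_polygon <- function(pts, poly, tol = 1e-7) {
  pts <- matrix(as.numeric(pts), ncol = 2L)
  n <- nrow(pts)
  if (is.null(poly) || nrow(poly) < 3L) return(integer(n))
  px <- pts[, 1L]; py <- pts[, 2L]
  m <- nrow(poly)
  inside <- logical(n)
  mind2 <- rep(Inf, n)
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
    x2 <- poly[j, 1L]; y2 <- poly[j, 2L]
    # even-odd crossing of the horizontal ray toward +x
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xc <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      inside <- xor(inside, crosses & px < xc)
    }
    # squared distance to the segment
    vx <- x2 - x1; vy <- y2 - y1
    L2 <- vx^2 + vy^2
    t <- if (L2 > 0) pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / L2)) else 0
    dx <- px - (x1 + t * vx); dy <- py - (y1 + t * vy)
    mind2 <- pmin(mind2, dx^2 + dy^2)
  }
  res <- ifelse(mind2 <= tol^2, 2L, ifelse(inside, 1L, 0L))
  as.integer(res)
}
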