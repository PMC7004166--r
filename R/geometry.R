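# Spherical geometry helpers shared by the preprocessing, metrics and
# covariate modules. All distances are in kilometres on a sphere of mean
# Earth radius 6371.0088 km.

#' Mean Earth radius (km) used throughout the package
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle (orthodromic) distance via the haversine formula
#'
#' Vectorised over all four coordinate arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @param radius_km Sphere radius in km; default the mean Earth radius.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = EARTH_RADIUS_KM) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  a <- pmin(pmax(a, 0), 1)
  2 * radius_km * asin(sqrt(a))
}

#' Azimuthal equidistant projection centred on a reference point
#'
#' Projects WGS84 coordinates onto a local plane (km east/north of the
#' centre). Distances from the centre and all azimuths are preserved, which
#' keeps daily-scale geometry (a few tens of km) essentially undistorted.
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @param center Numeric length-2 vector c(lat0, lon0) of the projection
#'   centre in degrees.
#' @return Data frame with columns `x`, `y` in km.
#' @export
aeqd_project <- function(lat, lon, center) {
  rad <- pi / 180
  phi <- lat * rad; lam <- lon * rad
  phi0 <- center[1] * rad; lam0 <- center[2] * rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(pmax(cosc, -1), 1)
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  data.frame(x = x, y = y)
}

#' Inverse azimuthal equidistant projection
#'
#' @param x,y Planar coordinates in km as produced by [aeqd_project()].
#' @param center Numeric length-2 vector c(lat0, lon0) in degrees.
#' @return Data frame with columns `lat`, `lon` in degrees.
#' @export
aeqd_inverse <- function(x, y, center) {
  rad <- pi / 180
  phi0 <- center[1] * rad; lam0 <- center[2] * rad
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_KM
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cosc * sin(phi0) + y * sinc * cos(phi0) / rho))
  lam <- ifelse(rho < 1e-12, lam0,
                lam0 + atan2(x * sinc, rho * cos(phi0) * cosc - y * sin(phi0) * sinc))
  data.frame(lat = phi / rad, lon = lam / rad)
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd rule on planar coordinates. Suitable for
#' the small polygons (protected-area boundaries) handled here; points on
#' an edge may fall either side at machine precision.
#'
#' @param px,py Point coordinates (vectorised).
#' @param poly_x,poly_y Polygon vertex coordinates (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  stopifnot(n >= 3, length(poly_y) == n)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
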