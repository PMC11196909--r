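#' Mean Earth radius (IUGG), kilometers
#'
#' Radius of the sphere on which all great-circle distances in this package
#' are computed.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between WGS84 coordinates
#'
#' Haversine distance on a sphere of radius [EARTH_RADIUS_KM]. All arguments
#' are vectorised and recycled; coordinates are decimal degrees.
#'
#' @param lat1,lon1 coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 coordinates of the second point(s), decimal degrees.
#' @param radius_km sphere radius in kilometers.
#' @return numeric vector of distances in kilometers.
#' @examples
#' great_circle_km(0, 0, 1, 0) # one degree of latitude, ~111.195 km
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2, radius_km = EARTH_RADIUS_KM) {
  stopifnot(
    all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE),
    all(abs(lon1) <= 180, na.rm = TRUE), all(abs(lon2) <= 180, na.rm = TRUE)
  )
  d2r <- pi / 180
  phi1 <- lat1 * d2r
  phi2 <- lat2 * d2r
  dphi <- (lat2 - lat1) * d2r
  dlam <- (lon2 - lon1) * d2r
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  # clamp against floating-point overshoot for near-antipodal pairs
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

# Displace (lat, lon) by a bearing (degrees) and distance (km) on the same
# sphere the distance functions use, so generated displacements are exact
# under the pipeline's own metric. Returns a matrix with columns lat, lon.
destination_point <- function(lat, lon, bearing_deg, distance_km) {
  p <- geosphere::destPoint(
    cbind(lon, lat), bearing_deg, distance_km * 1000,
    r = EARTH_RADIUS_KM * 1000
  )
  cbind(lat = p[, 2], lon = p[, 1])
}
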