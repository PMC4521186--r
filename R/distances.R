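#' Mean Earth radius used throughout the package (km)
#'
#' All great-circle computations in this package use a spherical Earth with
#' this radius, so distances are reproducible to the last bit across
#' platforms.
#'
#' @format A single numeric value, 6371.0 km.
#' @export
EARTH_RADIUS_KM <- 6371.0

.check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop("coordinates must be finite", call. = FALSE)
  if (any(lat < -90 | lat > 90))
    stop("latitude out of range [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon >= 360))
    stop("longitude out of range", call. = FALSE)
  invisible(TRUE)
}

#' Great-circle distance between points (haversine)
#'
#' Spherical distance in km between coordinate pairs, vectorised and
#' recycled like [base::pmax()]. Uses the haversine formula on a sphere of
#' radius [EARTH_RADIUS_KM], which is numerically stable for both very
#' small and antipodal separations.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' great_circle_km(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  .check_coords(lat1, lon1)
  .check_coords(lat2, lon2)
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dphi <- (lat2 - lat1) * pi / 180
  dlam <- (lon2 - lon1) * pi / 180
  a <- sin(dphi / 2)^2 + cos(p1) * cos(p2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

# unit vectors on the sphere; rows are points
.to_xyz <- function(lat, lon) {
  phi <- lat * pi / 180; lam <- lon * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

.to_latlon <- function(xyz) {
  n <- sqrt(rowSums(xyz^2))
  xyz <- xyz / n
  lat <- asin(pmin(pmax(xyz[, 3], -1), 1)) * 180 / pi
  lon <- atan2(xyz[, 2], xyz[, 1]) * 180 / pi
  lon[lon >= 180] <- lon[lon >= 180] - 360
  cbind(lat = lat, lon = lon)
}

# central angle between unit vectors via the chord, equals the haversine
# distance when scaled by the radius
.chord_angle <- function(chord) 2 * asin(pmin(chord / 2, 1))
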