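# Spherical-Earth geodesy helpers shared across modules.
# All conversions use R = 6371 km so that advection, path lengths and
# buffer geometry agree with each other.

#' Earth radius used throughout the package (meters)
#'
#' Spherical Earth, 6371 km, so that degree/meter conversion in the
#' advection core, haversine path lengths, and metric buffering are all
#' mutually consistent.
#' @keywords internal
EARTH_RADIUS_M <- 6371000

.deg2rad <- function(x) x * pi / 180

# meters per degree of latitude (constant on the sphere)
.m_per_deg_lat <- function() EARTH_RADIUS_M * pi / 180

# meters per degree of longitude at latitude `lat` (degrees)
.m_per_deg_lon <- function(lat) EARTH_RADIUS_M * cos(.deg2rad(lat)) * pi / 180

#' Great-circle distance in kilometers
#'
#' Haversine distance on a spherical Earth of radius 6371 km, vectorized
#' over coordinate pairs.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @examples
#' gc_dist_km(0, 0, 1, 0) # one degree along the equator, ~111.19 km
#' @export
gc_dist_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M) / 1000
}

# Local tangent-plane (azimuthal equidistant-style) projection about
# (lon0, lat0): x east, y north, meters. Adequate at the O(10-100 km)
# scales where it is used (buffer geometry, KDE coordinates).
.to_tangent_m <- function(lon, lat, lon0, lat0) {
  list(x = (lon - lon0) * .m_per_deg_lon(lat0),
       y = (lat - lat0) * .m_per_deg_lat())
}

.from_tangent_m <- function(x, y, lon0, lat0) {
  list(lon = lon0 + x / .m_per_deg_lon(lat0),
       lat = lat0 + y / .m_per_deg_lat())
}

#' Point-in-polygon test
#'
#' Vectorized membership test of points in a single polygon ring
#' (closed or open; closure is handled). Wraps [mgcv::in.out()].
#'
#' @param lon,lat point coordinates (degrees).
#' @param polygon two-column matrix of ring vertices (lon, lat).
#' @return logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygon) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2)
  bnd <- polygon
  if (!all(bnd[1, ] == bnd[nrow(bnd), ])) bnd <- rbind(bnd, bnd[1, ])
  mgcv::in.out(bnd, cbind(as.numeric(lon), as.numeric(lat)))
}
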