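#' Gridded, time-varying ocean fields
#'
#' `ocean_grid()` builds the container used by the Lagrangian core: eastward
#' and northward velocity and temperature on a regular lon/lat(/depth) grid
#' with a land mask, over a strictly increasing time axis. Internally the
#' variable arrays are stored with dimensions (lon, lat, depth, time);
#' [write_ocean_grid()] serializes them in the conventional
#' (time, depth, lat, lon) order with units attributes.
#'
#' @param lon,lat strictly increasing coordinate vectors, decimal degrees.
#' @param time strictly increasing times, seconds since experiment start.
#' @param u,v eastward/northward velocity (m/s), arrays of dimension
#'   `c(length(lon), length(lat), length(depth), length(time))`; 2-D or 3-D
#'   arrays are recycled along missing depth/time axes when those have
#'   length one.
#' @param temp temperature (degrees C), same shape as `u`.
#' @param mask logical (lon x lat) matrix, `TRUE` = sea, `FALSE` = land.
#'   Default: all sea.
#' @param depth depth levels, meters positive down. Default single surface
#'   layer at 15 m (the midpoint of a 1-30 m release layer).
#' @param w optional upward velocity (m/s), same shape as `u`.
#' @return an object of class `ocean_grid`.
#' @seealso [make_uniform_jet()], [make_solid_body_rotation()],
#'   [make_boundary_current_system()], [interpolate_field()]
#' @export
ocean_grid <- function(lon, lat, time, u, v, temp, mask = NULL,
                       depth = 15, w = NULL) {
  stopifnot(length(lon) >= 2, length(lat) >= 2, length(time) >= 1)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0))
    stop("lon and lat must be strictly increasing")
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time must be strictly increasing")
  if (length(depth) > 1 && any(diff(depth) <= 0))
    stop("depth must be strictly increasing (positive down)")
  dims <- c(length(lon), length(lat), length(depth), length(time))
  expand <- function(a, name) {
    if (is.null(a)) return(NULL)
    a <- as.array(a)
    if (length(dim(a)) == 2) dim(a) <- c(dim(a), 1, 1)
    if (length(dim(a)) == 3) dim(a) <- c(dim(a), 1)
    if (!all(dim(a)[1:2] == dims[1:2]))
      stop(sprintf("%s has lon/lat dims %s, expected %s", name,
                   paste(dim(a)[1:2], collapse = "x"),
                   paste(dims[1:2], collapse = "x")))
    if (dim(a)[3] == 1 && dims[3] > 1) a <- a[, , rep(1, dims[3]), , drop = FALSE]
    if (dim(a)[4] == 1 && dims[4] > 1) a <- a[, , , rep(1, dims[4]), drop = FALSE]
    if (!all(dim(a) == dims)) stop(name, ": dimension mismatch")
    a
  }
  u <- expand(u, "u"); v <- expand(v, "v"); temp <- expand(temp, "temp")
  w <- expand(w, "w")
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  mask <- matrix(as.logical(mask), dims[1], dims[2])
  sea <- which(mask)
  for (nm in c("u", "v", "temp")) {
    a <- get(nm)
    slab <- matrix(a, nrow = dims[1] * dims[2])[sea, , drop = FALSE]
    if (any(!is.finite(slab)))
      stop(nm, " must be finite over sea cells")
  }
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat),
                 depth = as.numeric(depth), time = as.numeric(time),
                 u = u, v = v, w = w, temp = temp, mask = mask,
                 units = c(lon = "degrees_east", lat = "degrees_north",
                           depth = "m", time = "s", u = "m s-1",
                           v = "m s-1", w = "m s-1", temp = "degC")),
            class = "ocean_grid")
}

#' @export
print.ocean_grid <- function(x, ...) {
  cat(sprintf(
    "<ocean_grid> %d x %d x %d x %d (lon x lat x depth x time)\n",
    length(x$lon), length(x$lat), length(x$depth), length(x$time)))
  cat(sprintf("  lon  [%.3f, %.3f] degE   lat [%.3f, %.3f] degN\n",
              min(x$lon), max(x$lon), min(x$lat), max(x$lat)))
  cat(sprintf("  time [%g, %g] s   sea fraction %.2f\n",
              min(x$time), max(x$time), mean(x$mask)))
  invisible(x)
}

#' Regular grid specification helper
#'
#' Convenience constructor for the coordinate axes handed to the synthetic
#' field generators.
#'
#' @param lon_range,lat_range numeric length-2, degrees.
#' @param dlon,dlat grid spacing, degrees.
#' @param duration_days length of the time axis, days.
#' @param frame_seconds spacing of stored field frames, seconds.
#' @param depth depth levels (m, positive down).
#' @return a list with components `lon`, `lat`, `time`, `depth`.
#' @export
grid_spec <- function(lon_range, lat_range, dlon = 0.5, dlat = 0.5,
                      duration_days = 90, frame_seconds = 86400,
                      depth = 15) {
  stopifnot(diff(lon_range) > 0, diff(lat_range) > 0, dlon > 0, dlat > 0)
  list(lon = seq(lon_range[1], lon_range[2], by = dlon),
       lat = seq(lat_range[1], lat_range[2], by = dlat),
       time = seq(0, duration_days * 86400, by = frame_seconds),
       depth = depth)
}

#' Write/read gridded fields as a self-describing JSON container
#'
#' Fields are stored with CF-style metadata: named dimensions in
#' (time, depth, lat, lon) order, coordinate vectors, per-variable units
#' attributes, and the land mask. This plain-text container plays the role
#' a NetCDF file plays in larger pipelines and round-trips exactly.
#'
#' @param grid an [ocean_grid()].
#' @param path file path.
#' @return `write_ocean_grid()` returns `path` invisibly;
#'   `read_ocean_grid()` returns an `ocean_grid`.
#' @export
write_ocean_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ocean_grid"))
  to_cf <- function(a) if (is.null(a)) NULL else aperm(a, c(4, 3, 2, 1))
  doc <- list(
    conventions = "CF-like-JSON-1",
    dimensions = list(time = length(grid$time), depth = length(grid$depth),
                      lat = length(grid$lat), lon = length(grid$lon)),
    dim_order = c("time", "depth", "lat", "lon"),
    coordinates = list(lon = grid$lon, lat = grid$lat,
                       depth = grid$depth, time = grid$time),
    units = as.list(grid$units),
    variables = list(u = as.vector(to_cf(grid$u)),
                     v = as.vector(to_cf(grid$v)),
                     temp = as.vector(to_cf(grid$temp)),
                     w = if (is.null(grid$w)) NULL else as.vector(to_cf(grid$w)),
                     mask = as.vector(t(grid$mask))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ocean_grid
#' @export
read_ocean_grid <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- doc$dimensions
  cf_dims <- c(d$time, d$depth, d$lat, d$lon)
  from_cf <- function(v) {
    if (is.null(v) || length(v) == 0) return(NULL)
    aperm(array(v, cf_dims), c(4, 3, 2, 1))
  }
  mask <- matrix(as.logical(doc$variables$mask), nrow = d$lat)
  ocean_grid(lon = doc$coordinates$lon, lat = doc$coordinates$lat,
             time = doc$coordinates$time, depth = doc$coordinates$depth,
             u = from_cf(doc$variables$u), v = from_cf(doc$variables$v),
             temp = from_cf(doc$variables$temp),
             w = from_cf(doc$variables$w), mask = t(mask))
}
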