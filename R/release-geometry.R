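# Release and destination geometry: source areas built by merging metric
# buffers around platform positions, proportional allocation of released
# larvae, uniform sampling of release positions, and coastal receiving
# areas with shelf areas.

#' Read a platform coordinate table
#'
#' CSV with header `id,lon,lat,basin`. A synthetic stand-in for a real
#' platform inventory ships with the package
#' (`system.file("extdata", "platforms_synthetic.csv", package = "larvadrift")`).
#'
#' @param path CSV path.
#' @return data.frame with columns id (character), lon, lat (degrees),
#'   basin (character).
#' @export
read_platforms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lon", "lat", "basin")
  if (!all(need %in% names(df)))
    stop("platform table must have columns ", paste(need, collapse = ","))
  df$id <- as.character(df$id)
  df[, need]
}

# tangent-plane rasterization of a union of equal-radius discs around the
# member platforms of one connected component; returns area (km2) and an
# approximate boundary polygon in lon/lat.
.disc_union_geometry <- function(lon, lat, radius_km, cells_per_radius = 40) {
  lon0 <- mean(lon); lat0 <- mean(lat)
  p <- .to_tangent_m(lon, lat, lon0, lat0)
  r <- radius_km * 1000
  h <- r / cells_per_radius
  gx <- seq(min(p$x) - 1.2 * r, max(p$x) + 1.2 * r, by = h)
  gy <- seq(min(p$y) - 1.2 * r, max(p$y) + 1.2 * r, by = h)
  inside <- matrix(FALSE, length(gx), length(gy))
  for (k in seq_along(p$x)) {
    dx2 <- (gx - p$x[k])^2
    dy2 <- (gy - p$y[k])^2
    inside <- inside | outer(dx2, dy2, "+") <= r^2
  }
  area_km2 <- sum(inside) * h^2 / 1e6
  cl <- grDevices::contourLines(gx, gy, inside + 0, levels = 0.5)
  ring <- cl[[which.max(vapply(cl, function(c) length(c$x), 1))]]
  ll <- .from_tangent_m(ring$x, ring$y, lon0, lat0)
  list(area_km2 = area_km2,
       polygon = cbind(lon = ll$lon, lat = ll$lat))
}

#' Merge metric buffers around platforms into source areas
#'
#' Each source area is a connected component of the union of geodesic discs
#' of `radius_km` around the platforms: two discs are merged when their
#' centers are closer than twice the radius, and overlap chains propagate
#' (connected-component union). Areas are ordered by southernmost, then
#' westernmost member platform.
#'
#' @param platforms data.frame with id, lon, lat, basin (see
#'   [read_platforms()]).
#' @param radius_km buffer radius, km (default 9, matching an
#'   eddy-resolving 1/12-degree grid cell).
#' @param mask optional [ocean_grid()] whose land mask is used to warn
#'   about platforms on land (they are kept: platforms are offshore
#'   structures and the warning flags a geometry/domain mismatch).
#' @return object of class `source_areas`: a list of areas, each with
#'   `id`, `platform_ids`, `basin` (majority vote of members), `lon`/`lat`
#'   member coordinates, `polygon` (lon/lat ring), `area_km2`,
#'   `release_count` (NA until [allocate_particles()]), plus attribute
#'   `radius_km`.
#' @export
merge_platform_buffers <- function(platforms, radius_km = 9, mask = NULL) {
  stopifnot(radius_km > 0, nrow(platforms) >= 1)
  if (!is.null(mask) && inherits(mask, "ocean_grid")) {
    i <- pmin(pmax(findInterval(platforms$lon, .cell_edges(mask$lon)),
                   1L), length(mask$lon))
    j <- pmin(pmax(findInterval(platforms$lat, .cell_edges(mask$lat)),
                   1L), length(mask$lat))
    onland <- !mask$mask[cbind(i, j)]
    if (any(onland))
      warning(sum(onland), " platform(s) fall on land cells; kept")
  }
  n <- nrow(platforms)
  dmat <- geosphere::distm(cbind(platforms$lon, platforms$lat),
                           fun = geosphere::distHaversine) / 1000
  adj <- dmat < 2 * radius_km
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  areas <- lapply(unique(comp), function(cid) {
    m <- which(comp == cid)
    geom <- .disc_union_geometry(platforms$lon[m], platforms$lat[m],
                                 radius_km)
    basins <- platforms$basin[m]
    list(platform_ids = platforms$id[m],
         basin = names(sort(table(basins), decreasing = TRUE))[1],
         lon = platforms$lon[m], lat = platforms$lat[m],
         polygon = geom$polygon, area_km2 = geom$area_km2,
         release_count = NA_integer_)
  })
  # deterministic ordering: southernmost, then westernmost member
  key <- t(vapply(areas, function(a) c(min(a$lat), min(a$lon)), numeric(2)))
  ord <- order(key[, 1], key[, 2])
  areas <- areas[ord]
  for (i in seq_along(areas)) areas[[i]]$id <- i
  structure(areas, class = "source_areas", radius_km = radius_km)
}

#' @export
print.source_areas <- function(x, ...) {
  cat(sprintf("<source_areas> %d areas from %d platforms (radius %g km)\n",
              length(x), sum(vapply(x, function(a) length(a$platform_ids), 1)),
              attr(x, "radius_km")))
  invisible(x)
}

#' Summarize source areas as a data.frame
#' @param x a `source_areas` object.
#' @param ... unused.
#' @return data.frame with one row per source area.
#' @export
as.data.frame.source_areas <- function(x, ...) {
  do.call(rbind, lapply(x, function(a)
    data.frame(id = a$id, basin = a$basin,
               n_platforms = length(a$platform_ids),
               area_km2 = a$area_km2,
               release_count = a$release_count)))
}

#' Allocate released larvae proportionally to source-area size
#'
#' Counts are proportional to polygon area with largest-remainder rounding,
#' so they sum exactly to `total`. Allocation is scale-free: it depends on
#' area ratios only.
#'
#' @param source_areas a [merge_platform_buffers()] result.
#' @param total total number of larvae to release (>= number of areas).
#' @return the `source_areas` object with `release_count` filled in.
#' @export
allocate_particles <- function(source_areas, total) {
  stopifnot(inherits(source_areas, "source_areas"),
            total >= length(source_areas))
  areas <- vapply(source_areas, function(a) a$area_km2, 1)
  if (sum(areas) <= 0) stop("total source area is zero")
  quota <- total * areas / sum(areas)
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  for (i in seq_along(source_areas))
    source_areas[[i]]$release_count <- as.integer(base[i])
  source_areas
}

#' Sample release positions inside one source area
#'
#' Horizontal positions are uniform over the merged-buffer region
#' (rejection sampling in the bounding box, membership tested against the
#' exact union of member discs); release depth is uniform in `depth_range`.
#'
#' @param area one element of a `source_areas` object.
#' @param n number of larvae (defaults to the area's `release_count`).
#' @param depth_range release depth interval, meters (default 1-30 m).
#' @param seed integer seed.
#' @param radius_km disc radius used for membership; defaults to the
#'   radius the areas were built with when called via
#'   [release_particles()].
#' @return data.frame of initial particle states: id, source_area, basin,
#'   lon, lat, depth, age (0), status ("alive"), cumulative_distance (0).
#' @export
sample_release_positions <- function(area, n = area$release_count,
                                     depth_range = c(1, 30), seed = 1L,
                                     radius_km = 9) {
  stopifnot(n >= 0, length(depth_range) == 2)
  if (is.na(n)) stop("release_count not set; call allocate_particles()")
  bb_lon <- range(area$polygon[, 1]); bb_lat <- range(area$polygon[, 2])
  if (diff(bb_lon) <= 0 || diff(bb_lat) <= 0)
    stop("degenerate source-area polygon")
  set.seed(seed)
  lon <- numeric(0); lat <- numeric(0)
  r_m <- radius_km * 1000
  while (length(lon) < n) {
    m <- max(2 * (n - length(lon)), 100)
    cl <- runif(m, bb_lon[1], bb_lon[2])
    ca <- runif(m, bb_lat[1], bb_lat[2])
    d <- geosphere::distm(cbind(cl, ca), cbind(area$lon, area$lat),
                          fun = geosphere::distHaversine)
    keep <- apply(d <= r_m, 1, any)
    lon <- c(lon, cl[keep]); lat <- c(lat, ca[keep])
  }
  lon <- lon[seq_len(n)]; lat <- lat[seq_len(n)]
  data.frame(id = seq_len(n), source_area = area$id,
             basin = area$basin, lon = lon, lat = lat,
             depth = runif(n, depth_range[1], depth_range[2]),
             age = 0, status = "alive", cumulative_distance = 0,
             stringsAsFactors = FALSE)
}

#' Release larvae from every source area
#'
#' @param source_areas allocated `source_areas`.
#' @param depth_range release depth interval (m).
#' @param seed integer base seed; each area uses `seed + id`.
#' @return data.frame of all initial particle states with globally unique
#'   ids.
#' @export
release_particles <- function(source_areas, depth_range = c(1, 30),
                              seed = 1L) {
  radius <- attr(source_areas, "radius_km")
  out <- lapply(source_areas, function(a) {
    if (a$release_count == 0) return(NULL)
    sample_release_positions(a, a$release_count, depth_range,
                             seed = seed + a$id, radius_km = radius)
  })
  df <- do.call(rbind, out)
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Idealized coastal receiving areas
#'
#' Builds disjoint shelf strips along a meridional coastline: each strip is
#' bounded landward by `coast_lon`, seaward by a fixed shelf width standing
#' in for the 200-m isobath, and alongshore by consecutive `basin_breaks`
#' latitudes. Shelf areas are computed with spherical geometry.
#'
#' @param basin_breaks strictly increasing latitudes (length = number of
#'   areas + 1).
#' @param coast_lon coastline longitude (degrees).
#' @param shelf_width_km seaward extent of each strip (km).
#' @param ids area identifiers, south to north; defaults to the twelve
#'   Brazilian coastal zones (PEL, SAN, CAM, ES, BA, SEAL, PEPB, POT, CE,
#'   BAR, PAMA, AM) when twelve areas are requested.
#' @return object of class `receiving_areas`: list of areas with `id`,
#'   `polygon` (lon/lat ring), `shelf_area_km2`.
#' @export
build_receiving_areas <- function(basin_breaks, coast_lon,
                                  shelf_width_km = 60, ids = NULL) {
  if (any(diff(basin_breaks) <= 0))
    stop("basin_breaks must be strictly increasing (overlapping breaks)")
  n <- length(basin_breaks) - 1
  if (is.null(ids)) {
    ids <- if (n == 12)
      c("PEL", "SAN", "CAM", "ES", "BA", "SEAL",
        "PEPB", "POT", "CE", "BAR", "PAMA", "AM")
    else sprintf("RA%02d", seq_len(n))
  }
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  areas <- lapply(seq_len(n), function(i) {
    la0 <- basin_breaks[i]; la1 <- basin_breaks[i + 1]
    latm <- (la0 + la1) / 2
    lon1 <- coast_lon + shelf_width_km * 1000 / .m_per_deg_lon(latm)
    ring <- cbind(lon = c(coast_lon, lon1, lon1, coast_lon, coast_lon),
                  lat = c(la0, la0, la1, la1, la0))
    # spherical-Earth area to stay consistent with the advection geodesy;
    # geosphere warns that its ellipsoidal algorithm differs
    a <- suppressWarnings(
      geosphere::areaPolygon(ring[1:4, ], r = EARTH_RADIUS_M)) / 1e6
    list(id = ids[i], polygon = ring, shelf_area_km2 = a)
  })
  structure(areas, class = "receiving_areas")
}

#' Receiving areas from user-supplied polygons
#'
#' @param polygons named list of two-column lon/lat rings (pairwise
#'   disjoint).
#' @return a `receiving_areas` object; shelf areas by spherical geometry.
#' @export
receiving_areas_from_polygons <- function(polygons) {
  stopifnot(length(polygons) >= 1, !is.null(names(polygons)))
  areas <- lapply(names(polygons), function(nm) {
    ring <- polygons[[nm]]
    list(id = nm, polygon = ring,
         shelf_area_km2 =
           suppressWarnings(
             geosphere::areaPolygon(ring, r = EARTH_RADIUS_M)) / 1e6)
  })
  structure(areas, class = "receiving_areas")
}

#' Assign positions to receiving areas
#'
#' @param lon,lat positions (degrees); depth is ignored by design
#'   (destinations are map positions).
#' @param receiving_areas a `receiving_areas` object.
#' @return character vector of area ids, `NA` where a position falls in no
#'   area. Errors if any position falls in two areas (overlapping
#'   polygons).
#' @export
assign_receiving_area <- function(lon, lat, receiving_areas) {
  stopifnot(inherits(receiving_areas, "receiving_areas"))
  out <- rep(NA_character_, length(lon))
  if (length(lon) == 0) return(out)
  for (ra in receiving_areas) {
    inside <- point_in_polygon(lon, lat, ra$polygon)
    if (any(inside & !is.na(out)))
      stop("receiving-area polygons overlap at a query point")
    out[inside] <- ra$id
  }
  out
}
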