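# Connectivity and dispersal statistics computed from trajectory sets and
# geometry: mortality by advection, larval-supply matrices, source-basin
# effectiveness, per-km2 incidence on receiving areas, great-circle path
# lengths, kernel density surfaces, and rank-based group comparisons.

#' Mortality by advection per source area
#'
#' For each group, MA = (sum of larvae advected outside the domain) /
#' (sum of larvae released). Computed by recounting raw per-particle
#' statuses, so it serves as the independent check on the incremental
#' death counters a simulation maintains.
#'
#' @param final a [final_states()] data.frame (optionally with extra
#'   `season`/`year` columns).
#' @param group_by grouping columns, default `"source_area"`.
#' @return data.frame of class `mortality_table` with columns for the
#'   grouping, `d_sa` (released), `a_sa` (advected out) and `MA`.
#' @export
mortality_by_advection <- function(final, group_by = "source_area") {
  stopifnot(all(group_by %in% names(final)))
  if (any(is.na(final$source_area))) stop("unknown source tag")
  out <- stats::aggregate(
    cbind(d_sa = rep(1L, nrow(final)),
          a_sa = as.integer(final$status == "dead_advection")),
    by = final[group_by], FUN = sum)
  out <- out[do.call(order, out[group_by]), , drop = FALSE]
  rownames(out) <- NULL
  out$MA <- out$a_sa / out$d_sa
  class(out) <- c("mortality_table", "data.frame")
  out
}

#' Larval-supply matrix
#'
#' A larva "reaches" a receiving area iff it is alive at the end of the
#' run and its final-day position lies inside the area's polygon. The
#' larval-supply percentage attributes each receiving area's arrivals to
#' source areas:
#' `LS(SA, RA) = 100 * arrivals(SA, RA) / total arrivals at RA`.
#'
#' @param final a [final_states()] data.frame.
#' @param receiving_areas a `receiving_areas` object.
#' @return object of class `supply_matrix`: list with `arrivals` (counts,
#'   source areas x receiving areas) and `LS` (percentages; columns with
#'   arrivals sum to 100, empty columns are NA).
#' @export
larval_supply_matrix <- function(final, receiving_areas) {
  alive <- final[final$status == "alive", ]
  ra <- assign_receiving_area(alive$final_lon, alive$final_lat,
                              receiving_areas)
  ra_ids <- vapply(receiving_areas, function(a) a$id, "")
  sa_ids <- sort(unique(final$source_area))
  arrivals <- table(factor(alive$source_area, levels = sa_ids),
                    factor(ra, levels = ra_ids))
  arrivals <- matrix(as.integer(arrivals), nrow = length(sa_ids),
                     dimnames = list(source_area = as.character(sa_ids),
                                     receiving_area = ra_ids))
  tot <- colSums(arrivals)
  LS <- 100 * sweep(arrivals, 2, ifelse(tot > 0, tot, NA), "/")
  structure(list(arrivals = arrivals, LS = LS),
            class = "supply_matrix")
}

#' @export
print.supply_matrix <- function(x, ...) {
  cat(sprintf("<supply_matrix> %d source areas x %d receiving areas, %d arrivals\n",
              nrow(x$arrivals), ncol(x$arrivals), sum(x$arrivals)))
  invisible(x)
}

#' Effectiveness of each source basin in supplying the coast
#'
#' The percentage of all larvae released from a basin that are alive at
#' the end of the run with a final position inside any receiving area.
#'
#' @param final a [final_states()] data.frame.
#' @param receiving_areas a `receiving_areas` object.
#' @return data.frame with `basin`, `released`, `reached`,
#'   `effectiveness_pct`.
#' @export
effectiveness <- function(final, receiving_areas) {
  ra <- rep(NA_character_, nrow(final))
  alive <- final$status == "alive"
  ra[alive] <- assign_receiving_area(final$final_lon[alive],
                                     final$final_lat[alive],
                                     receiving_areas)
  reached <- !is.na(ra)
  agg <- stats::aggregate(cbind(released = rep(1, nrow(final)),
                                reached = as.integer(reached)),
                          by = list(basin = final$basin), FUN = sum)
  agg$effectiveness_pct <- 100 * agg$reached / agg$released
  agg
}

#' Arrivals per square kilometer of receiving-area shelf
#'
#' Raw arrival counts corrected for differences in continental-shelf area.
#'
#' @param final a [final_states()] data.frame.
#' @param receiving_areas a `receiving_areas` object.
#' @return data.frame with `receiving_area`, `arrivals`, `shelf_area_km2`,
#'   `per_km2`.
#' @export
arrivals_per_km2 <- function(final, receiving_areas) {
  sm <- larval_supply_matrix(final, receiving_areas)
  cnt <- colSums(sm$arrivals)
  shelf <- vapply(receiving_areas, function(a) a$shelf_area_km2, 1)
  stopifnot(all(shelf > 0))
  data.frame(receiving_area = names(cnt), arrivals = as.integer(cnt),
             shelf_area_km2 = shelf, per_km2 = cnt / shelf,
             row.names = NULL)
}

#' Total great-circle path length of a trajectory
#'
#' Sum of haversine segment lengths (spherical Earth, R = 6371 km) between
#' successive recorded positions — a path length, not a net displacement.
#'
#' @param lon,lat recorded positions (degrees), in time order.
#' @return distance in km.
#' @export
total_distance <- function(lon, lat) {
  stopifnot(length(lon) == length(lat), length(lon) >= 1)
  if (length(lon) == 1) return(0)
  sum(gc_dist_km(lon[-length(lon)], lat[-length(lat)], lon[-1], lat[-1]))
}

#' Pooled recorded positions of (by default) surviving larvae
#'
#' Helper extracting the positions fed to [kernel_density()]: every
#' recorded position of every particle while it is alive at that record
#' (set `alive_only = FALSE` to pool everything).
#'
#' @param ts a `trajectory_set`.
#' @param alive_only keep only records where the particle is alive.
#' @return data.frame with lon, lat.
#' @export
recorded_positions <- function(ts, alive_only = TRUE) {
  keep <- if (alive_only) ts$status == 0L else !is.na(ts$lon)
  data.frame(lon = ts$lon[keep], lat = ts$lat[keep])
}

#' Kernel density surface of larval positions
#'
#' Gaussian product-kernel density over the domain, computed in
#' tangent-plane kilometers (so the bandwidth is metric) and normalized to
#' integrate to one over the evaluation grid. Bandwidth defaults to
#' Scott's rule per axis.
#'
#' @param lon,lat pooled positions (degrees), >= 2 points with nonzero
#'   spread on both axes.
#' @param lon_range,lat_range evaluation domain (degrees).
#' @param n grid nodes per axis.
#' @param bandwidth_km optional length-2 metric bandwidth (sd of the
#'   Gaussian kernel, km); default Scott's rule.
#' @return object of class `density_surface`: `lon`, `lat` grid vectors,
#'   matrix `z` (density per km2, lon x lat), `bandwidth_km`,
#'   `integral` (should be 1 up to grid discretization).
#' @export
kernel_density <- function(lon, lat, lon_range = range(lon),
                           lat_range = range(lat), n = 128,
                           bandwidth_km = NULL) {
  stopifnot(length(lon) >= 2)
  if (stats::sd(lon) == 0 || stats::sd(lat) == 0)
    stop("positions have zero variance on one axis; no density surface")
  lon0 <- mean(lon_range); lat0 <- mean(lat_range)
  p <- .to_tangent_m(lon, lat, lon0, lat0)
  x <- p$x / 1000; y <- p$y / 1000
  xr <- (lon_range - lon0) * .m_per_deg_lon(lat0) / 1000
  yr <- (lat_range - lat0) * .m_per_deg_lat() / 1000
  if (is.null(bandwidth_km)) {
    npts <- length(x)
    bandwidth_km <- c(stats::sd(x), stats::sd(y)) * npts^(-1 / 6)
  }
  # MASS::kde2d divides h by 4 internally: pass 4*sd for a Gaussian kernel
  # with the requested standard deviation
  kd <- MASS::kde2d(x, y, h = 4 * bandwidth_km, n = n,
                    lims = c(xr, yr))
  cell <- diff(kd$x)[1] * diff(kd$y)[1]
  z <- kd$z / (sum(kd$z) * cell)
  glon <- lon0 + kd$x * 1000 / .m_per_deg_lon(lat0)
  glat <- lat0 + kd$y * 1000 / .m_per_deg_lat()
  structure(list(lon = glon, lat = glat, z = z,
                 bandwidth_km = bandwidth_km,
                 integral = sum(z) * cell),
            class = "density_surface")
}

#' Write a density surface to a self-describing JSON container
#' @param ds a `density_surface`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_surface <- function(ds, path) {
  doc <- list(dimensions = list(lon = length(ds$lon), lat = length(ds$lat)),
              dim_order = c("lon", "lat"),
              coordinates = list(lon = ds$lon, lat = ds$lat),
              units = list(z = "km-2", bandwidth = "km"),
              bandwidth_km = ds$bandwidth_km,
              variables = list(z = as.vector(ds$z)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rank-based comparison of groups
#'
#' Two groups: two-sided Mann-Whitney (Wilcoxon rank-sum) test; three or
#' more: Kruskal-Wallis. Both use tie-corrected statistics and a 5%
#' significance level.
#'
#' @param values numeric observations.
#' @param groups grouping factor (>= 2 non-empty groups).
#' @param alpha significance level.
#' @return data.frame with `method`, `statistic`, `p_value`,
#'   `significant`.
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  counts <- table(groups)
  if (nlevels(groups) < 2 || any(counts == 0))
    stop("need at least two non-empty groups")
  if (nlevels(groups) == 2) {
    ht <- stats::wilcox.test(values ~ groups, exact = FALSE,
                             correct = FALSE)
    method <- "mann-whitney"
  } else {
    ht <- stats::kruskal.test(values, groups)
    method <- "kruskal-wallis"
  }
  data.frame(method = method, statistic = unname(ht$statistic),
             p_value = ht$p.value, significant = ht$p.value < alpha)
}

#' Fraction of larvae ending north of their release latitude
#'
#' Seasonal diagnostic of the bifurcating boundary-current system: under
#' the winter phase the bifurcation sits farther south, so a larger share
#' of mid-latitude releases is entrained in the equatorward jet and ends
#' north of where it started.
#'
#' @param final a [final_states()] data.frame.
#' @param alive_only restrict to surviving larvae.
#' @return fraction in [0, 1].
#' @export
northward_fraction <- function(final, alive_only = TRUE) {
  if (alive_only) final <- final[final$status == "alive", ]
  if (nrow(final) == 0) return(NA_real_)
  mean(final$final_lat > final$release_lat)
}
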