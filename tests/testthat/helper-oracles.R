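# Shared fixtures and independent oracles used across the suite.

# small steady grids for oracle fields
small_spec <- function(lon = c(0, 10), lat = c(-3, 3), d = 0.5,
                       days = 30) {
  grid_spec(lon, lat, dlon = d, dlat = d, duration_days = days)
}

# Brute-force multilinear interpolator: plain nested loops over corners,
# written independently of interpolate_field() (same land conventions:
# land corners contribute zero velocity unrenormalized; temperature is
# renormalized over sea corners).
brute_interp <- function(grid, lon, lat, t, var) {
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  nt <- length(grid$time)
  renorm <- var == "temp"
  vapply(seq_along(lon), function(q) {
    i <- max(1, min(findInterval(lon[q], grid$lon), nlon - 1))
    j <- max(1, min(findInterval(lat[q], grid$lat), nlat - 1))
    wx <- (lon[q] - grid$lon[i]) / (grid$lon[i + 1] - grid$lon[i])
    wy <- (lat[q] - grid$lat[j]) / (grid$lat[j + 1] - grid$lat[j])
    if (nt == 1) { its <- 1; wts <- 1 } else {
      it <- max(1, min(findInterval(t, grid$time), nt - 1))
      wt <- (t - grid$time[it]) / (grid$time[it + 1] - grid$time[it])
      its <- c(it, it + 1); wts <- c(1 - wt, wt)
    }
    val <- 0; wsum <- 0
    for (a in seq_along(its)) {
      for (di in 0:1) for (dj in 0:1) {
        w <- wts[a] * (if (di == 0) 1 - wx else wx) *
          (if (dj == 0) 1 - wy else wy)
        sea <- grid$mask[i + di, j + dj]
        v <- grid[[var]][i + di, j + dj, 1, its[a]]
        if (sea) { val <- val + w * v; wsum <- wsum + w }
      }
    }
    if (renorm) { if (wsum > 0) val / wsum else NA_real_ } else val
  }, numeric(1))
}

# Brute-force disc-union component count: O(n^2) repeated transitive
# closure on the "discs overlap" relation, no graph library.
brute_union_count <- function(lon, lat, radius_km) {
  n <- length(lon)
  comp <- seq_len(n)
  d <- geosphere::distm(cbind(lon, lat),
                        fun = geosphere::distHaversine) / 1000
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (d[a, b] < 2 * radius_km && comp[b] != comp[a]) {
        old <- comp[b]
        comp[comp == old] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  length(unique(comp))
}

# convenience: run a small simulation on the default synthetic world
run_toy_experiment <- function(season = "winter", n = 1000, days = 10,
                               seed = 11, dlon = 1, dlat = 1,
                               eps = 1e-9) {
  dom <- default_domain(dlon = dlon, dlat = dlat, duration_days = days)
  g <- make_boundary_current_system(
    circulation_params(eddy_length_scale = 150), dom$spec,
    season_phase(season), coast_lon = dom$coast_lon)
  sas <- merge_platform_buffers(synthetic_platform_table(), 9)
  sas <- allocate_particles(sas, n)
  parts <- release_particles(sas, seed = seed)
  cfg <- simulation_config(total_particles = n, pld_days = days,
                           turbulent_dissipation = eps, seed = seed)
  list(grid = g, source_areas = sas, config = cfg,
       ts = run_simulation(cfg, g, parts))
}
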