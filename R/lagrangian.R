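# Lagrangian core: field interpolation, RK4 advection, turbulent random
# walk, reflecting coastline, mortality rules, and the 90-day individual-
# based simulation loop. All per-step operations are vectorized over
# particles.

STATUS_LEVELS <- c("alive", "dead_advection", "dead_temperature")

#' Simulation configuration
#'
#' Biophysical parameters of a one-release experiment. Defaults follow the
#' standard sun-coral configuration: 70,000 released larvae over the source
#' areas, a 90-day pelagic larval duration, death below (or at) 12.5 degC
#' or on advection across the open boundary, RK4 advection with a 1800-s
#' step, an Okubo-scaled turbulent random walk driven by a turbulent
#' dissipation rate of 1e-9 m2 s-3, and bouncing (reflecting, non-lethal)
#' coastline behaviour.
#'
#' @param total_particles total larvae released per experiment.
#' @param pld_days pelagic larval duration (days): particles stop at this
#'   age.
#' @param lethal_temp lethal temperature (degC); a particle sampling
#'   `temp <= lethal_temp` dies (inclusive threshold).
#' @param turbulent_dissipation turbulent dissipation rate epsilon
#'   (m2 s-3); 0 disables the random walk.
#' @param larval_density larval density metadata, kg m-3; carried in
#'   provenance, not used dynamically (a buoyancy model would additionally
#'   need a larval diameter).
#' @param dt advection time step, seconds; must divide `record_stride` and
#'   satisfy the CFL constraint for the field.
#' @param record_stride interval between recorded trajectory points,
#'   seconds (default daily).
#' @param coastline_behavior only `"bouncing"` is implemented: particles
#'   reflect off land and never die from coast contact.
#' @param advection only `"rk4"` is implemented.
#' @param seed integer seed for the turbulent walk.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(total_particles = 70000L,
                              pld_days = 90,
                              lethal_temp = 12.5,
                              turbulent_dissipation = 1e-9,
                              larval_density = 1016,
                              dt = 1800,
                              record_stride = 86400,
                              coastline_behavior = "bouncing",
                              advection = "rk4",
                              seed = 1L) {
  stopifnot(total_particles > 0, pld_days > 0, dt > 0,
            turbulent_dissipation >= 0)
  if (record_stride %% dt != 0)
    stop("dt must divide record_stride")
  coastline_behavior <- match.arg(coastline_behavior, "bouncing")
  advection <- match.arg(advection, "rk4")
  structure(as.list(environment()), class = "simulation_config")
}

# cell edges for a node-centered axis (midpoints, extended half a cell)
.cell_edges <- function(x) {
  dx0 <- x[2] - x[1]; dxn <- x[length(x)] - x[length(x) - 1]
  c(x[1] - dx0 / 2, (x[-1] + x[-length(x)]) / 2, x[length(x)] + dxn / 2)
}

#' Interpolate gridded fields at particle positions
#'
#' Multilinear interpolation in lon/lat (and depth when the grid has more
#' than one level), linear in time. Land nodes contribute zero velocity
#' with no renormalization (flow stalls smoothly toward the coast);
#' temperature is renormalized over sea nodes so coastal particles sample
#' water temperature, not land zeros.
#'
#' @param grid an [ocean_grid()].
#' @param lon,lat,depth query positions (vectors).
#' @param t query time (seconds, scalar); must lie within the grid's time
#'   span.
#' @return list with components `u`, `v`, `temp` (NA outside the
#'   horizontal hull) and `in_domain` (logical).
#' @export
interpolate_field <- function(grid, lon, lat, depth = NULL, t) {
  stopifnot(inherits(grid, "ocean_grid"), length(t) == 1)
  if (t < min(grid$time) - 1e-9 || t > max(grid$time) + 1e-9)
    stop("query time outside the field's time span")
  n <- length(lon)
  inside <- lon >= grid$lon[1] & lon <= grid$lon[length(grid$lon)] &
    lat >= grid$lat[1] & lat <= grid$lat[length(grid$lat)]
  out <- list(u = rep(NA_real_, n), v = rep(NA_real_, n),
              temp = rep(NA_real_, n), in_domain = inside)
  if (!any(inside)) return(out)
  qlon <- lon[inside]; qlat <- lat[inside]
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  nd <- length(grid$depth); nt <- length(grid$time)

  i <- pmin(pmax(findInterval(qlon, grid$lon), 1L), nlon - 1L)
  j <- pmin(pmax(findInterval(qlat, grid$lat), 1L), nlat - 1L)
  wx <- (qlon - grid$lon[i]) / (grid$lon[i + 1] - grid$lon[i])
  wy <- (qlat - grid$lat[j]) / (grid$lat[j + 1] - grid$lat[j])

  if (nt == 1) { it <- 1L; wt <- 0 } else {
    it <- pmin(pmax(findInterval(t, grid$time), 1L), nt - 1L)
    wt <- (t - grid$time[it]) / (grid$time[it + 1] - grid$time[it])
  }
  if (nd == 1 || is.null(depth)) { kd <- 1L; wz <- 0 } else {
    qd <- depth[inside]
    kd <- pmin(pmax(findInterval(qd, grid$depth), 1L), nd - 1L)
    wz <- (qd - grid$depth[kd]) / (grid$depth[kd + 1] - grid$depth[kd])
    wz <- pmin(pmax(wz, 0), 1)
  }

  sea <- grid$mask
  # accumulate over the 4 spatial corners (x2 depth levels, x2 time frames)
  tw <- if (nt == 1) list(list(l = it, w = 1)) else
    list(list(l = it, w = 1 - wt), list(l = it + 1L, w = wt))
  kw <- if (nd == 1) list(list(l = 1L, w = 1)) else
    list(list(l = kd, w = 1 - wz), list(l = kd + 1L, w = wz))
  gather <- function(arr, renorm) {
    val <- 0; wsum <- 0
    for (tl in tw) for (kl in kw) {
      for (di in 0:1) for (dj in 0:1) {
        ii <- i + di; jj <- j + dj
        wxy <- (if (di == 0) 1 - wx else wx) *
               (if (dj == 0) 1 - wy else wy)
        wcor <- wxy * tl$w * kl$w
        sflag <- sea[cbind(ii, jj)]
        # linear index into [lon, lat, depth, time]
        lin <- ii + (jj - 1L) * nlon +
          (kl$l - 1L) * nlon * nlat + (tl$l - 1L) * nlon * nlat * nd
        vv <- arr[lin]
        val <- val + ifelse(sflag, wcor * vv, 0)
        if (renorm) wsum <- wsum + ifelse(sflag, wcor, 0)
      }
    }
    if (renorm) ifelse(wsum > 0, val / wsum, NA_real_) else val
  }
  out$u[inside] <- gather(grid$u, renorm = FALSE)
  out$v[inside] <- gather(grid$v, renorm = FALSE)
  out$temp[inside] <- gather(grid$temp, renorm = TRUE)
  out
}

#' One classical RK4 advection step
#'
#' Four-stage Runge-Kutta on the interpolated velocity with degree/meter
#' conversion at each stage's latitude. Any stage sampling outside the
#' horizontal hull marks the particle as exited, with the offending stage
#' position returned.
#'
#' @param lon,lat current positions (degrees), vectors over particles.
#' @param depth depths (m), or NULL for a single-level grid.
#' @param grid an [ocean_grid()].
#' @param t step start time (s).
#' @param dt step length (s).
#' @return list `lon`, `lat` (proposed positions) and `exited` (logical).
#' @export
rk4_step <- function(lon, lat, depth = NULL, grid, t, dt) {
  stopifnot(dt > 0)
  n <- length(lon)
  exited <- rep(FALSE, n)
  stage <- function(plon, plat, tt) {
    f <- interpolate_field(grid, plon, plat, depth, tt)
    exited <<- exited | !f$in_domain
    dlon <- ifelse(f$in_domain, f$u / .m_per_deg_lon(plat), 0)
    dlat <- ifelse(f$in_domain, f$v / .m_per_deg_lat(), 0)
    list(dlon = dlon, dlat = dlat)
  }
  k1 <- stage(lon, lat, t)
  k2 <- stage(lon + 0.5 * dt * k1$dlon, lat + 0.5 * dt * k1$dlat, t + dt / 2)
  k3 <- stage(lon + 0.5 * dt * k2$dlon, lat + 0.5 * dt * k2$dlat, t + dt / 2)
  k4 <- stage(lon + dt * k3$dlon, lat + dt * k3$dlat, t + dt)
  list(lon = lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
       lat = lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat),
       exited = exited)
}

#' Turbulent random-walk displacement
#'
#' Isotropic horizontal random walk with per-axis standard deviation
#' `sqrt(2 * K_h * dt)`, where the horizontal diffusivity follows the
#' Okubo 4/3 scaling `K_h = epsilon^(1/3) * l^(4/3)` with `l` the grid
#' cell size (the horizontal-dispersion scheme used by individual-based
#' larval models). `epsilon = 0` disables the walk.
#'
#' @param n number of particles.
#' @param epsilon turbulent dissipation rate (m2 s-3).
#' @param cell_size_m grid cell size l (m).
#' @param dt time step (s).
#' @return list `dx`, `dy` in meters (exact zeros when `epsilon = 0`).
#' @export
turbulent_displacement <- function(n, epsilon, cell_size_m, dt) {
  stopifnot(epsilon >= 0)
  if (epsilon == 0 || n == 0)
    return(list(dx = numeric(n), dy = numeric(n)))
  kh <- okubo_diffusivity(epsilon, cell_size_m)
  sd <- sqrt(2 * kh * dt)
  list(dx = stats::rnorm(n, 0, sd), dy = stats::rnorm(n, 0, sd))
}

#' Okubo 4/3-scaled horizontal diffusivity
#' @param epsilon turbulent dissipation rate (m2 s-3).
#' @param cell_size_m length scale l (m).
#' @return K_h in m2 s-1.
#' @export
okubo_diffusivity <- function(epsilon, cell_size_m) {
  epsilon^(1 / 3) * cell_size_m^(4 / 3)
}

#' Reflect proposed positions off the coastline ("bouncing")
#'
#' If a proposed position falls on a land cell, the crossing component of
#' the displacement is mirrored about the face of the land cell that was
#' crossed (longitude face, latitude face, or both); if every reflection
#' still lands on land the particle stays put. Particles never die from
#' coast contact.
#'
#' @param old_lon,old_lat accepted positions from the previous step (must
#'   be on sea cells).
#' @param new_lon,new_lat proposed positions.
#' @param grid an [ocean_grid()] providing the land mask.
#' @return list `lon`, `lat` of accepted positions.
#' @export
apply_coastline_bounce <- function(old_lon, old_lat, new_lon, new_lat,
                                   grid) {
  edges_x <- .cell_edges(grid$lon)
  edges_y <- .cell_edges(grid$lat)
  nlon <- length(grid$lon); nlat <- length(grid$lat)
  cell <- function(lon, lat) {
    i <- pmin(pmax(findInterval(lon, edges_x), 1L), nlon)
    j <- pmin(pmax(findInterval(lat, edges_y), 1L), nlat)
    cbind(i, j)
  }
  on_land <- function(lon, lat) {
    # outside the hull counts as sea here: domain exit is handled by the
    # mortality rule, not the coastline
    inside <- lon >= edges_x[1] & lon <= edges_x[nlon + 1] &
      lat >= edges_y[1] & lat <= edges_y[nlat + 1]
    ol <- rep(FALSE, length(lon))
    if (any(inside)) {
      cc <- cell(lon[inside], lat[inside])
      ol[inside] <- !grid$mask[cc]
    }
    ol
  }
  if (any(on_land(old_lon, old_lat)))
    stop("invariant violation: particle starts a step on land")
  lon <- new_lon; lat <- new_lat
  bad <- on_land(lon, lat)
  if (!any(bad)) return(list(lon = lon, lat = lat))
  idx <- which(bad)
  co <- cell(old_lon[idx], old_lat[idx])
  cn <- cell(lon[idx], lat[idx])
  # face between the old (sea) cell and the proposed (land) cell
  face_x <- ifelse(cn[, 1] > co[, 1], edges_x[pmax(cn[, 1], 1)],
            ifelse(cn[, 1] < co[, 1], edges_x[co[, 1]], NA))
  face_y <- ifelse(cn[, 2] > co[, 2], edges_y[pmax(cn[, 2], 1)],
            ifelse(cn[, 2] < co[, 2], edges_y[co[, 2]], NA))
  ref_lon <- ifelse(is.na(face_x), lon[idx], 2 * face_x - lon[idx])
  ref_lat <- ifelse(is.na(face_y), lat[idx], 2 * face_y - lat[idx])
  cand <- list(cbind(ref_lon, lat[idx]),      # reflect zonal component
               cbind(lon[idx], ref_lat),      # reflect meridional
               cbind(ref_lon, ref_lat))       # reflect both
  acc_lon <- old_lon[idx]; acc_lat <- old_lat[idx]  # fallback: stay
  done <- rep(FALSE, length(idx))
  for (cd in cand) {
    ok <- !done & !on_land(cd[, 1], cd[, 2])
    acc_lon[ok] <- cd[ok, 1]; acc_lat[ok] <- cd[ok, 2]
    done <- done | ok
  }
  lon[idx] <- acc_lon; lat[idx] <- acc_lat
  list(lon = lon, lat = lat)
}

#' Apply the mortality rules to one particle step
#'
#' Advection is checked before temperature: a particle advected outside
#' the domain has no defined temperature there. The temperature threshold
#' is inclusive (`temp <= lethal_temp` kills).
#'
#' @param in_domain logical: particle still inside the horizontal hull.
#' @param temp sampled temperature (degC; NA allowed when out of domain).
#' @param lethal_temp threshold (degC).
#' @return character status: "alive", "dead_advection" or
#'   "dead_temperature".
#' @export
apply_mortality <- function(in_domain, temp, lethal_temp = 12.5) {
  ifelse(!in_domain, "dead_advection",
         ifelse(!is.na(temp) & temp <= lethal_temp,
                "dead_temperature", "alive"))
}

#' Run the individual-based dispersal simulation
#'
#' Steps every particle through the field with, per step: RK4 advection,
#' turbulent displacement, coastline bounce, domain-exit check
#' (death by advection), temperature check (death at or below the lethal
#' threshold), ageing, and recording at the record stride. Path length is
#' accumulated from the recorded positions with great-circle segments.
#' Dead particles stop moving; the status census is conserved at every
#' record. A fixed seed makes the run bit-reproducible.
#'
#' @param config a [simulation_config()].
#' @param grid an [ocean_grid()].
#' @param particles initial particle states from [release_particles()].
#' @param verbose log a particle-status census every 10 simulated days.
#' @return object of class `trajectory_set`: record `times` (s), matrices
#'   `lon`, `lat`, `status`, `cumulative_distance` of dimension
#'   (particles x records), the per-source-area incremental death
#'   `counters` maintained during the run, the release table, config and
#'   provenance hash.
#' @export
run_simulation <- function(config, grid, particles, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(grid, "ocean_grid"))
  if (!all(particles$status == "alive") || !all(particles$age == 0))
    stop("initial particles must be alive with age 0")
  # CFL: one advective step must not exceed one grid cell
  cell_m <- min(diff(grid$lon)[1] * .m_per_deg_lon(max(abs(grid$lat))),
                diff(grid$lat)[1] * .m_per_deg_lat())
  vmax <- max(abs(grid$u), abs(grid$v), na.rm = TRUE)
  if (vmax * config$dt > cell_m)
    stop(sprintf(
      "CFL violation: max speed %.2f m/s * dt %g s exceeds cell size %.0f m",
      vmax, config$dt, cell_m))

  duration <- min(config$pld_days * 86400, max(grid$time))
  n_steps <- floor(duration / config$dt)
  rec_every <- config$record_stride / config$dt
  rec_times <- seq(0, n_steps * config$dt, by = config$record_stride)
  n <- nrow(particles); nr <- length(rec_times)

  lon <- particles$lon; lat <- particles$lat; depth <- particles$depth
  status <- rep(0L, n)   # 0 alive, 1 dead_advection, 2 dead_temperature
  cum <- numeric(n)
  R_lon <- matrix(NA_real_, n, nr); R_lat <- matrix(NA_real_, n, nr)
  R_st <- matrix(0L, n, nr); R_cum <- matrix(0, n, nr)
  R_lon[, 1] <- lon; R_lat[, 1] <- lat
  last_lon <- lon; last_lat <- lat
  counters <- matrix(0L, nrow = length(unique(particles$source_area)),
                     ncol = 2,
                     dimnames = list(sort(unique(particles$source_area)),
                                     c("dead_advection", "dead_temperature")))
  sa_chr <- as.character(particles$source_area)
  set.seed(config$seed)
  eps <- config$turbulent_dissipation
  rec_i <- 1L
  for (s in seq_len(n_steps)) {
    t0 <- (s - 1) * config$dt
    alive <- which(status == 0L)
    if (length(alive) > 0) {
      st <- rk4_step(lon[alive], lat[alive], depth[alive], grid,
                     t0, config$dt)
      plon <- st$lon; plat <- st$lat
      mv <- !st$exited
      if (eps > 0 && any(mv)) {
        tb <- turbulent_displacement(sum(mv), eps, cell_m, config$dt)
        plon[mv] <- plon[mv] + tb$dx / .m_per_deg_lon(plat[mv])
        plat[mv] <- plat[mv] + tb$dy / .m_per_deg_lat()
      }
      if (any(mv)) {
        b <- apply_coastline_bounce(lon[alive][mv], lat[alive][mv],
                                    plon[mv], plat[mv], grid)
        plon[mv] <- b$lon; plat[mv] <- b$lat
      }
      f <- interpolate_field(grid, plon, plat, depth[alive],
                             min(t0 + config$dt, max(grid$time)))
      new_status <- apply_mortality(!st$exited & f$in_domain, f$temp,
                                    config$lethal_temp)
      lon[alive] <- plon; lat[alive] <- plat
      died_adv <- alive[new_status == "dead_advection"]
      died_tmp <- alive[new_status == "dead_temperature"]
      status[died_adv] <- 1L; status[died_tmp] <- 2L
      if (length(died_adv))
        counters[, 1] <- counters[, 1] +
          as.integer(table(factor(sa_chr[died_adv],
                                  levels = rownames(counters))))
      if (length(died_tmp))
        counters[, 2] <- counters[, 2] +
          as.integer(table(factor(sa_chr[died_tmp],
                                  levels = rownames(counters))))
    }
    if (s %% rec_every == 0) {
      rec_i <- rec_i + 1L
      seg <- gc_dist_km(last_lon, last_lat, lon, lat)
      cum <- cum + seg
      last_lon <- lon; last_lat <- lat
      R_lon[, rec_i] <- lon; R_lat[, rec_i] <- lat
      R_st[, rec_i] <- status; R_cum[, rec_i] <- cum
      if (verbose && (rec_times[rec_i] %% (10 * 86400) == 0))
        message(sprintf("day %3.0f: alive %d, dead_advection %d, dead_temperature %d",
                        rec_times[rec_i] / 86400, sum(status == 0),
                        sum(status == 1), sum(status == 2)))
    }
  }
  structure(list(times = rec_times, lon = R_lon, lat = R_lat,
                 status = R_st, cumulative_distance = R_cum,
                 particles = particles, counters = counters,
                 config = config, seed = config$seed,
                 config_hash = rlang::hash(config)),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  st <- x$status[, ncol(x$status)]
  cat(sprintf("<trajectory_set> %d particles, %d records (%.0f days)\n",
              nrow(x$lon), length(x$times), max(x$times) / 86400))
  cat(sprintf("  final census: alive %d, dead_advection %d, dead_temperature %d\n",
              sum(st == 0), sum(st == 1), sum(st == 2)))
  invisible(x)
}

#' Final per-particle states
#'
#' One row per particle: provenance, final recorded position, status at the
#' end of the run, and total great-circle path length.
#'
#' @param ts a `trajectory_set`.
#' @return data.frame with id, source_area, basin, release_lon,
#'   release_lat, final_lon, final_lat, status, distance_km.
#' @export
final_states <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  nr <- length(ts$times)
  data.frame(id = ts$particles$id,
             source_area = ts$particles$source_area,
             basin = ts$particles$basin,
             release_lon = ts$particles$lon,
             release_lat = ts$particles$lat,
             final_lon = ts$lon[, nr], final_lat = ts$lat[, nr],
             status = STATUS_LEVELS[ts$status[, nr] + 1L],
             distance_km = ts$cumulative_distance[, nr],
             stringsAsFactors = FALSE)
}

#' Write trajectories to a self-describing JSON container and CSV summary
#'
#' @param ts a `trajectory_set`.
#' @param path output path for the array container (JSON).
#' @param summary_path optional CSV path for the flat per-particle summary.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path, summary_path = NULL) {
  doc <- list(dimensions = list(particle = nrow(ts$lon),
                                time = length(ts$times)),
              dim_order = c("particle", "time"),
              times = ts$times,
              units = list(time = "s", lon = "degrees_east",
                           lat = "degrees_north",
                           cumulative_distance = "km"),
              status_levels = STATUS_LEVELS,
              variables = list(lon = as.vector(ts$lon),
                               lat = as.vector(ts$lat),
                               status = as.vector(ts$status),
                               cumulative_distance =
                                 as.vector(ts$cumulative_distance)),
              provenance = list(seed = ts$seed,
                                config_hash = ts$config_hash))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!is.null(summary_path))
    utils::write.csv(final_states(ts), summary_path, row.names = FALSE)
  invisible(path)
}
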