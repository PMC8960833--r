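test_that("interpolation reproduces node values and midpoint means", {
  sp <- small_spec(days = 2)
  g <- make_boundary_current_system(
    circulation_params(eddy_band_lat_range = c(-2, 2), jet_width = 100,
                       eddy_length_scale = 120, seed = 5),
    sp, season_phase("summer"), coast_lon = sp$lon[3])
  # exactly at a node and frame time
  i <- 10; j <- 5; it <- 2
  f <- interpolate_field(g, g$lon[i], g$lat[j], t = g$time[it])
  expect_equal(f$u, g$u[i, j, 1, it], tolerance = 1e-12)
  expect_equal(f$temp, g$temp[i, j, 1, it], tolerance = 1e-12)
  # midpoint of two all-sea nodes differing only in u
  gu <- make_uniform_jet(0, 0, sp)
  gu$u[i, j, , ] <- 1; gu$u[i + 1, j, , ] <- 3
  f <- interpolate_field(gu, (gu$lon[i] + gu$lon[i + 1]) / 2, gu$lat[j],
                         t = 0)
  expect_equal(f$u, 2, tolerance = 1e-12)
})

test_that("interpolation agrees with a brute-force oracle", {
  sp <- small_spec(days = 2)
  g <- make_boundary_current_system(
    circulation_params(eddy_band_lat_range = c(-2, 2), jet_width = 100,
                       eddy_length_scale = 120, seed = 5),
    sp, season_phase("summer"), coast_lon = sp$lon[3])
  set.seed(99)
  n <- 1000
  qlon <- runif(n, min(g$lon), max(g$lon))
  qlat <- runif(n, min(g$lat), max(g$lat))
  t <- 1.37 * 86400
  f <- interpolate_field(g, qlon, qlat, t = t)
  for (var in c("u", "v", "temp")) {
    oracle <- brute_interp(g, qlon, qlat, t, var)
    expect_equal(f[[var]], oracle, tolerance = 1e-12)
  }
})

test_that("out-of-domain queries are flagged, bad times rejected", {
  g <- make_uniform_jet(0.1, 0, small_spec(days = 2))
  f <- interpolate_field(g, c(5, 100), c(0, 0), t = 0)
  expect_equal(f$in_domain, c(TRUE, FALSE))
  expect_true(is.na(f$u[2]))
  expect_error(interpolate_field(g, 5, 0, t = 1e9), "time span")
})

test_that("RK4 is exact on constant fields and inert on zero fields", {
  g <- make_uniform_jet(0.5, 0, small_spec(days = 2))
  st <- rk4_step(1, 0, NULL, g, 0, 3600)
  expect_equal((st$lon - 1) * pi / 180 * 6371000, 1800, tolerance = 1e-6)
  g0 <- make_uniform_jet(0, 0, small_spec(days = 2))
  st0 <- rk4_step(1, 0.5, NULL, g0, 0, 3600)
  expect_equal(c(st0$lon, st0$lat), c(1, 0.5))
})

test_that("solid-body orbit closes within 0.1% radius drift per period", {
  omega <- 2 * pi / 86400
  sp <- grid_spec(c(-2, 2), c(-2, 2), dlon = 0.1, dlat = 0.1,
                  duration_days = 2)
  g <- make_solid_body_rotation(omega, c(0, 0), sp)
  lon <- 100000 / (pi / 180 * 6371000)  # 100 km east of center
  p <- c(lon, 0); dt <- 1800
  for (s in seq_len(86400 / dt)) {
    st <- rk4_step(p[1], p[2], NULL, g, (s - 1) * dt, dt)
    p <- c(st$lon, st$lat)
  }
  r1 <- gc_dist_km(p[1], p[2], 0, 0)
  expect_lt(abs(r1 - 100) / 100, 0.001)
})

test_that("RK4 self-convergence order lies between 3 and 5", {
  omega <- 2 * pi / 86400
  sp <- grid_spec(c(-2, 2), c(-2, 2), dlon = 0.1, dlat = 0.1,
                  duration_days = 2)
  g <- make_solid_body_rotation(omega, c(0, 0), sp)
  run <- function(dt) {
    p <- c(100000 / (pi / 180 * 6371000), 0)
    for (s in seq_len(86400 / dt)) {
      st <- rk4_step(p[1], p[2], NULL, g, (s - 1) * dt, dt)
      p <- c(st$lon, st$lat)
    }
    p
  }
  ref <- run(225)
  err <- function(p) sqrt(sum((p - ref)^2))
  e1 <- err(run(3600)); e2 <- err(run(1800))
  order <- log2(e1 / e2)
  expect_gt(order, 3); expect_lt(order, 5)
})

test_that("turbulent walk follows the Okubo variance law", {
  # epsilon = 0 disables the walk exactly
  z <- turbulent_displacement(10, 0, 9200, 1800)
  expect_identical(z$dx, numeric(10))
  kh <- okubo_diffusivity(1e-9, 9200)
  expect_equal(kh, 1e-3 * 9200^(4 / 3), tolerance = 1e-12)
  set.seed(123)
  dt <- 1800
  d <- turbulent_displacement(1e5, 1e-9, 9200, dt)
  expect_lt(abs(var(d$dx) - 2 * kh * dt) / (2 * kh * dt), 0.03)
  expect_lt(abs(var(d$dy) - 2 * kh * dt) / (2 * kh * dt), 0.03)
})

test_that("pure-diffusion ensemble variance grows linearly in time", {
  set.seed(5)
  n <- 2000; steps <- 40; dt <- 1800
  x <- numeric(n); v <- numeric(steps)
  for (s in seq_len(steps)) {
    x <- x + turbulent_displacement(n, 1e-9, 9200, dt)$dx
    v[s] <- var(x)
  }
  fit <- summary(lm(v ~ seq_len(steps)))
  expect_gt(fit$r.squared, 0.99)
})

test_that("coastline bouncing mirrors the crossing component", {
  # meridional coast: land west of lon = 1 cell edges
  sp <- grid_spec(c(0, 5), c(-2, 2), dlon = 0.5, dlat = 0.5,
                  duration_days = 1)
  mask <- outer(sp$lon > 0.9, rep(TRUE, length(sp$lat)))
  g <- ocean_grid(sp$lon, sp$lat, sp$time,
                  array(0, c(11, 9, 1, length(sp$time))),
                  array(0, c(11, 9, 1, length(sp$time))),
                  array(20, c(11, 9, 1, length(sp$time))), mask = mask)
  # the sea/land cell face between nodes 0.5 (land) and 1.0 (sea) is at
  # lon 0.75; overshoot by d = 0.05 deg must come back 0.05 short
  b <- apply_coastline_bounce(1.2, 0, 0.70, 0, g)
  expect_equal(b$lon, 0.80, tolerance = 1e-12)
  expect_equal(b$lat, 0)
  # a move staying at sea is untouched
  b2 <- apply_coastline_bounce(1.2, 0, 1.4, 0.2, g)
  expect_equal(c(b2$lon, b2$lat), c(1.4, 0.2))
  # starting on land violates the invariant
  expect_error(apply_coastline_bounce(0.2, 0, 1.2, 0, g), "invariant")
})

test_that("random steps along a straight coast never land particles", {
  sp <- grid_spec(c(0, 5), c(-2, 2), dlon = 0.5, dlat = 0.5,
                  duration_days = 1)
  mask <- outer(sp$lon > 0.9, rep(TRUE, length(sp$lat)))
  g <- ocean_grid(sp$lon, sp$lat, sp$time,
                  array(0, c(11, 9, 1, length(sp$time))),
                  array(0, c(11, 9, 1, length(sp$time))),
                  array(20, c(11, 9, 1, length(sp$time))), mask = mask)
  edges_land <- 0.75
  set.seed(42)
  n <- 10000
  lon <- runif(n, 0.76, 1.3); lat <- runif(n, -1.5, 1.5)
  prop_lon <- lon + runif(n, -0.4, 0.4)
  prop_lat <- lat + runif(n, -0.4, 0.4)
  b <- apply_coastline_bounce(lon, lat, prop_lon, prop_lat, g)
  cell_i <- pmin(pmax(findInterval(b$lon, seq(-0.25, 5.25, by = 0.5)), 1), 11)
  cell_j <- pmin(pmax(findInterval(b$lat, seq(-2.25, 2.25, by = 0.5)), 1), 9)
  expect_true(all(g$mask[cbind(cell_i, cell_j)]))
})

test_that("mortality rules: precedence and inclusive threshold", {
  expect_equal(apply_mortality(FALSE, NA, 12.5), "dead_advection")
  # out of domain wins regardless of temperature
  expect_equal(apply_mortality(FALSE, 5, 12.5), "dead_advection")
  expect_equal(apply_mortality(TRUE, 12.5, 12.5), "dead_temperature")
  expect_equal(apply_mortality(TRUE, 12.6, 12.5), "alive")
})

test_that("quiet warm ocean: everyone lives and nobody moves", {
  sp <- small_spec(days = 5)
  g <- make_uniform_jet(0, 0, sp)
  parts <- data.frame(id = 1:50, source_area = 1, basin = "X",
                      lon = runif(50, 2, 8), lat = runif(50, -2, 2),
                      depth = 15, age = 0, status = "alive",
                      cumulative_distance = 0)
  cfg <- simulation_config(total_particles = 50, pld_days = 5,
                           turbulent_dissipation = 0, seed = 1)
  ts <- run_simulation(cfg, g, parts)
  fs <- final_states(ts)
  expect_true(all(fs$status == "alive"))
  expect_equal(fs$final_lon, parts$lon)
  expect_equal(fs$distance_km, rep(0, 50))
})

test_that("an out-flowing jet kills everyone by the predicted day", {
  sp <- small_spec(lon = c(0, 10), days = 25)
  g <- make_uniform_jet(-0.5, 0, sp)   # westward, exits lon = 0
  lon0 <- 5
  parts <- data.frame(id = 1:20, source_area = 1, basin = "X",
                      lon = lon0, lat = 0, depth = 15, age = 0,
                      status = "alive", cumulative_distance = 0)
  cfg <- simulation_config(total_particles = 20, pld_days = 25,
                           turbulent_dissipation = 0, seed = 1)
  ts <- run_simulation(cfg, g, parts)
  fs <- final_states(ts)
  expect_true(all(fs$status == "dead_advection"))
  # predicted exit: 5 deg at the equator / 0.5 m/s
  t_exit <- lon0 * pi / 180 * 6371000 / 0.5
  died <- apply(ts$status == 1L, 1, function(x) min(which(x)))
  t_died <- ts$times[died]
  expect_true(all(abs(t_died - t_exit) <= 86400 + cfg$dt))
})

test_that("a uniformly lethal ocean kills everyone at the first step", {
  sp <- small_spec(days = 2)
  g <- make_uniform_jet(0.1, 0, sp, temp = 10)
  parts <- data.frame(id = 1:10, source_area = 1, basin = "X",
                      lon = 5, lat = 0, depth = 15, age = 0,
                      status = "alive", cumulative_distance = 0)
  cfg <- simulation_config(total_particles = 10, pld_days = 2,
                           turbulent_dissipation = 0, seed = 1)
  ts <- run_simulation(cfg, g, parts)
  expect_true(all(ts$status[, 2] == 2L))
  expect_true(all(final_states(ts)$status == "dead_temperature"))
})

test_that("temperature exactly at the threshold is lethal", {
  sp <- small_spec(days = 2)
  g <- make_uniform_jet(0.1, 0, sp, temp = 12.5)
  parts <- data.frame(id = 1, source_area = 1, basin = "X",
                      lon = 5, lat = 0, depth = 15, age = 0,
                      status = "alive", cumulative_distance = 0)
  cfg <- simulation_config(total_particles = 1, pld_days = 2,
                           turbulent_dissipation = 0, seed = 1)
  fs <- final_states(run_simulation(cfg, g, parts))
  expect_equal(fs$status, "dead_temperature")
})

test_that("status census is conserved at every record", {
  out <- run_toy_experiment(n = 400, days = 8, seed = 21)
  ts <- out$ts
  census <- apply(ts$status, 2, function(s)
    sum(s == 0) + sum(s == 1) + sum(s == 2))
  expect_true(all(census == nrow(ts$lon)))
  # dead particles never move after death
  for (k in which(ts$status[, ncol(ts$status)] > 0)) {
    first_dead <- min(which(ts$status[k, ] > 0))
    if (first_dead < ncol(ts$status)) {
      expect_equal(ts$lon[k, first_dead:ncol(ts$lon)],
                   rep(ts$lon[k, first_dead], ncol(ts$lon) - first_dead + 1))
    }
  }
  # cumulative distance is non-decreasing
  expect_true(all(apply(ts$cumulative_distance, 1,
                        function(x) all(diff(x) >= -1e-9))))
})

test_that("no recorded alive position sits on land or outside the hull", {
  out <- run_toy_experiment(n = 400, days = 8, seed = 22)
  ts <- out$ts; g <- out$grid
  alive <- ts$status == 0L
  lon <- ts$lon[alive]; lat <- ts$lat[alive]
  expect_true(all(lon >= min(g$lon) & lon <= max(g$lon)))
  expect_true(all(lat >= min(g$lat) & lat <= max(g$lat)))
  ex <- larvadrift:::.cell_edges(g$lon); ey <- larvadrift:::.cell_edges(g$lat)
  ci <- pmin(pmax(findInterval(lon, ex), 1), length(g$lon))
  cj <- pmin(pmax(findInterval(lat, ey), 1), length(g$lat))
  expect_true(all(g$mask[cbind(ci, cj)]))
})

test_that("identical seeds give bit-identical runs", {
  a <- run_toy_experiment(n = 200, days = 5, seed = 31)$ts
  b <- run_toy_experiment(n = 200, days = 5, seed = 31)$ts
  expect_identical(a$lon, b$lon)
  expect_identical(a$status, b$status)
  expect_identical(a$cumulative_distance, b$cumulative_distance)
})

test_that("steady non-divergent flow keeps trajectories on streamlines", {
  # solid-body rotation: the streamfunction is the squared radius, so
  # radius drift over many orbits measures streamline fidelity
  omega <- 2 * pi / 86400
  sp <- grid_spec(c(-3, 3), c(-3, 3), dlon = 0.1, dlat = 0.1,
                  duration_days = 10)
  g <- make_solid_body_rotation(omega, c(0, 0), sp)
  p <- c(150000 / (pi / 180 * 6371000), 0); dt <- 1800
  for (s in seq_len(10 * 86400 / dt)) {
    st <- rk4_step(p[1], p[2], NULL, g, (s - 1) * dt, dt)
    p <- c(st$lon, st$lat)
  }
  r1 <- gc_dist_km(p[1], p[2], 0, 0)
  expect_lt(abs(r1 - 150) / 150, 0.01)
})

test_that("CFL violations abort with a diagnostic", {
  g <- make_uniform_jet(40, 0, small_spec(d = 0.25, days = 1))
  parts <- data.frame(id = 1, source_area = 1, basin = "X", lon = 5,
                      lat = 0, depth = 15, age = 0, status = "alive",
                      cumulative_distance = 0)
  cfg <- simulation_config(total_particles = 1, pld_days = 1, dt = 1800,
                           seed = 1)
  expect_error(run_simulation(cfg, g, parts), "CFL")
})

test_that("trajectory files round-trip provenance and arrays", {
  out <- run_toy_experiment(n = 100, days = 3, seed = 41)
  path <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(out$ts, path, csv)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(doc$dimensions$particle, 100)
  expect_equal(doc$provenance$config_hash, out$ts$config_hash)
  smry <- read.csv(csv)
  expect_equal(nrow(smry), 100)
  expect_true(all(smry$status %in%
                    c("alive", "dead_advection", "dead_temperature")))
})

test_that("config validation: dt must divide the record stride", {
  expect_error(simulation_config(dt = 1700), "divide")
  expect_s3_class(simulation_config(), "simulation_config")
})
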