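# Synthetic ocean fields: analytic oracle flows for verifying the advection
# core, and an idealized western-boundary-current system (seasonally
# migrating bifurcation feeding opposing alongshore jets, a mesoscale eddy
# band, a meridional temperature gradient) standing in for an eddy-resolving
# hindcast.

.eval_on_mesh <- function(spec, fun_uvt, mask = NULL) {
  nlon <- length(spec$lon); nlat <- length(spec$lat)
  nd <- length(spec$depth); nt <- length(spec$time)
  LON <- matrix(spec$lon, nlon, nlat)
  LAT <- matrix(spec$lat, nlon, nlat, byrow = TRUE)
  u <- array(0, c(nlon, nlat, nd, nt))
  v <- array(0, c(nlon, nlat, nd, nt))
  tp <- array(0, c(nlon, nlat, nd, nt))
  for (it in seq_len(nt)) {
    f <- fun_uvt(LON, LAT, spec$time[it])
    for (id in seq_len(nd)) {
      u[, , id, it] <- f$u; v[, , id, it] <- f$v; tp[, , id, it] <- f$temp
    }
  }
  ocean_grid(spec$lon, spec$lat, spec$time, u, v, tp,
             mask = mask, depth = spec$depth)
}

#' Solid-body rotation oracle field
#'
#' Steady flow u = -omega (y - y_c), v = omega (x - x_c) in local
#' tangent-plane meters about `center`. Trajectories are exact circles of
#' known period 2*pi/omega, which makes this the reference field for
#' advection accuracy and convergence tests.
#'
#' @param omega angular velocity, rad/s.
#' @param center numeric length-2 `(lon, lat)` of the rotation center.
#' @param spec a [grid_spec()] covering the rotation disc.
#' @param temp constant temperature assigned everywhere (degC).
#' @return an [ocean_grid()] (steady: single time frame is enough but the
#'   full requested time axis is honoured).
#' @export
make_solid_body_rotation <- function(omega, center, spec, temp = 25) {
  stopifnot(is.finite(omega), length(center) == 2)
  if (length(spec$lon) < 4 || length(spec$lat) < 4)
    stop("grid too coarse to resolve the rotation disc")
  fun <- function(LON, LAT, t) {
    p <- .to_tangent_m(LON, LAT, center[1], center[2])
    list(u = -omega * p$y, v = omega * p$x,
         temp = matrix(temp, nrow(LON), ncol(LON)))
  }
  .eval_on_mesh(spec, fun)
}

#' Spatially uniform jet oracle field
#'
#' Constant velocity everywhere, no land: displacement is exactly
#' (u0, v0) * t, so domain-exit times and advection mortality are
#' predictable in closed form.
#'
#' @param u0,v0 eastward/northward speed, m/s.
#' @param spec a [grid_spec()].
#' @param temp constant temperature (degC).
#' @return an [ocean_grid()].
#' @export
make_uniform_jet <- function(u0, v0, spec, temp = 25) {
  stopifnot(is.finite(u0), is.finite(v0))
  fun <- function(LON, LAT, t)
    list(u = matrix(u0, nrow(LON), ncol(LON)),
         v = matrix(v0, nrow(LON), ncol(LON)),
         temp = matrix(temp, nrow(LON), ncol(LON)))
  .eval_on_mesh(spec, fun)
}

#' Linear meridional temperature field
#'
#' Temperature varies linearly with latitude from `temp_equator` at the
#' warm edge to `temp_pole` at the cold edge, so any isotherm latitude is
#' available in closed form via [isotherm_lat()]. Velocities are zero.
#'
#' @param spec a [grid_spec()].
#' @param temp_equator,temp_pole temperatures at the warm/cold edge (degC);
#'   `temp_equator >= temp_pole`.
#' @param warm_edge which latitude edge is warm (`"north"` for a southern-
#'   hemisphere domain).
#' @return an [ocean_grid()] with `u = v = 0`.
#' @export
make_temperature_field <- function(spec, temp_equator, temp_pole,
                                   warm_edge = c("north", "south")) {
  warm_edge <- match.arg(warm_edge)
  stopifnot(temp_equator >= temp_pole)
  lat0 <- min(spec$lat); lat1 <- max(spec$lat)
  fun <- function(LON, LAT, t) {
    frac <- (LAT - lat0) / (lat1 - lat0)
    if (warm_edge == "south") frac <- 1 - frac
    list(u = LON * 0, v = LON * 0,
         temp = temp_pole + (temp_equator - temp_pole) * frac)
  }
  .eval_on_mesh(spec, fun)
}

#' Closed-form isotherm latitude of the linear temperature field
#'
#' @param temp_equator,temp_pole edge temperatures (degC).
#' @param lat_warm,lat_cold latitudes of the warm and cold edges (degrees).
#' @param iso isotherm value (degC), default the 12.5 degC lethal threshold.
#' @return latitude (degrees) at which temperature equals `iso`.
#' @export
isotherm_lat <- function(temp_equator, temp_pole, lat_warm, lat_cold,
                         iso = 12.5) {
  stopifnot(temp_equator >= temp_pole)
  if (temp_equator == temp_pole) return(NA_real_)
  lat_warm + (iso - temp_equator) / (temp_pole - temp_equator) *
    (lat_cold - lat_warm)
}

#' Circulation parameters for the idealized boundary-current system
#'
#' Defaults encode the regional picture the simulations emulate: a
#' bifurcation of the onshore equatorial inflow between 10 and 14 degS that
#' sits at its northernmost in austral summer and southernmost in austral
#' winter, an equatorward jet north of it and a poleward jet south of it
#' hugging the western land edge, a band of semi-permanent mesoscale eddies
#' between 20 and 30 degS trapping particles offshore, and a meridional
#' temperature gradient warm at the equatorward edge.
#'
#' @param bifurcation_lat_mean mean bifurcation latitude (deg).
#' @param bifurcation_seasonal_amplitude seasonal excursion (deg); the
#'   instantaneous bifurcation is mean + amplitude * season phase, with
#'   phase +1 in austral summer and -1 in austral winter.
#' @param jet_speed_north,jet_speed_south core speeds of the equatorward
#'   and poleward jets (m/s, both >= 0).
#' @param jet_width e-folding cross-shore width of the jets (km).
#' @param eddy_band_lat_range latitude range of the eddy band (deg, length 2).
#' @param eddy_amplitude eddy swirl velocity scale (m/s); 0 disables eddies.
#' @param eddy_length_scale eddy radius scale (km).
#' @param n_eddies number of Gaussian streamfunction bumps.
#' @param eddy_drift_mps slow zonal drift of eddy centers (m/s, westward
#'   negative).
#' @param onshore_speed westward inflow feeding the jets offshore (m/s).
#' @param temp_equator,temp_pole edge temperatures (degC).
#' @param seed integer seed making the random eddy field reproducible.
#' @return a list of class `circulation_params`.
#' @export
circulation_params <- function(bifurcation_lat_mean = -12,
                               bifurcation_seasonal_amplitude = 2,
                               jet_speed_north = 0.6,
                               jet_speed_south = 0.4,
                               jet_width = 150,
                               eddy_band_lat_range = c(-30, -20),
                               eddy_amplitude = 0.3,
                               eddy_length_scale = 100,
                               n_eddies = 12,
                               eddy_drift_mps = -0.03,
                               onshore_speed = 0.05,
                               temp_equator = 28,
                               temp_pole = 10,
                               seed = 1L) {
  stopifnot(jet_speed_north >= 0, jet_speed_south >= 0, jet_width > 0,
            eddy_amplitude >= 0, eddy_length_scale > 0,
            length(eddy_band_lat_range) == 2,
            temp_equator >= temp_pole)
  structure(as.list(environment()), class = "circulation_params")
}

#' Season phase functions
#'
#' One-release experiments are run within a single season, so the phase is
#' held constant: +1 for austral summer (bifurcation at its northernmost),
#' -1 for austral winter (southernmost). `season_phase_annual()` returns a
#' sinusoidal annual cycle peaking at the summer value at `t = 0`.
#'
#' @param season `"summer"` or `"winter"`.
#' @return a function of time (seconds) returning the phase in [-1, 1].
#' @export
season_phase <- function(season = c("summer", "winter")) {
  season <- match.arg(season)
  ph <- if (season == "summer") 1 else -1
  function(t) rep(ph, length(t))
}

#' @rdname season_phase
#' @export
season_phase_annual <- function() {
  function(t) cos(2 * pi * t / (365.25 * 86400))
}

#' Idealized western-boundary-current system
#'
#' Builds a time-varying [ocean_grid()]: a straight meridional coastline at
#' `coast_lon` (land to its west), an alongshore jet flowing equatorward
#' north of the instantaneous bifurcation latitude and poleward south of it,
#' confined within `jet_width` of the coast; a weak westward onshore inflow
#' offshore; a divergence-free mesoscale eddy field from a superposition of
#' Gaussian streamfunction bumps (tapered to zero at the coast so no flow
#' enters land) drifting slowly westward; and a linear meridional
#' temperature gradient warm at the northern edge.
#'
#' @param params a [circulation_params()].
#' @param spec a [grid_spec()].
#' @param phase_fun function of time (s) giving the seasonal phase in
#'   [-1, 1]; see [season_phase()].
#' @param coast_lon longitude of the coastline; default two cells in from
#'   the western grid edge.
#' @return an [ocean_grid()] with land mask west of `coast_lon`.
#' @export
make_boundary_current_system <- function(params, spec,
                                         phase_fun = season_phase("summer"),
                                         coast_lon = NULL) {
  stopifnot(inherits(params, "circulation_params"))
  if (is.null(coast_lon)) coast_lon <- spec$lon[3]
  if (params$eddy_amplitude > 0 &&
      (min(params$eddy_band_lat_range) < min(spec$lat) ||
       max(params$eddy_band_lat_range) > max(spec$lat)))
    stop("eddy band lies outside the grid")
  lat0 <- mean(range(spec$lat))
  mlon <- .m_per_deg_lon(lat0)          # tangent-plane meters per deg lon
  mlat <- .m_per_deg_lat()
  jw <- params$jet_width * 1000
  L <- params$eddy_length_scale * 1000
  if (params$eddy_amplitude > 0 &&
      L <= max(diff(spec$lon)[1] * mlon, diff(spec$lat)[1] * mlat))
    stop("eddy_length_scale must exceed the grid spacing")

  # reproducible eddy population
  eddies <- NULL
  if (params$eddy_amplitude > 0 && params$n_eddies > 0) {
    rs <- local({set.seed(params$seed); list(
      lon = runif(params$n_eddies,
                  coast_lon + 2 * L / mlon,
                  max(spec$lon) - L / mlon),
      lat = runif(params$n_eddies,
                  min(params$eddy_band_lat_range),
                  max(params$eddy_band_lat_range)),
      sgn = sample(c(-1, 1), params$n_eddies, replace = TRUE))})
    # streamfunction amplitude giving max swirl speed ~ eddy_amplitude
    rs$A <- rs$sgn * params$eddy_amplitude * L * exp(0.5)
    eddies <- rs
  }

  temp_grad <- function(LAT) {
    frac <- (LAT - min(spec$lat)) / diff(range(spec$lat))
    params$temp_pole + (params$temp_equator - params$temp_pole) * frac
  }

  fun <- function(LON, LAT, t) {
    bif <- params$bifurcation_lat_mean +
      params$bifurcation_seasonal_amplitude * phase_fun(t)[1]
    xoff <- (LON - coast_lon) * mlon          # m east of the coast
    sea <- xoff > 0
    cross <- exp(-(xoff / jw)^2)
    f <- 0.5 * (1 + tanh((LAT - bif) / 1.5))  # 1 north of bif, 0 south
    Vcore <- params$jet_speed_north * f - params$jet_speed_south * (1 - f)
    v <- Vcore * cross
    u <- -params$onshore_speed * (1 - cross)
    if (!is.null(eddies)) {
      taper <- 1 - exp(-(pmax(xoff, 0) / (1.5 * L))^2)
      dtaper <- exp(-(pmax(xoff, 0) / (1.5 * L))^2) *
        2 * pmax(xoff, 0) / (1.5 * L)^2
      for (k in seq_along(eddies$A)) {
        dx <- xoff - ((eddies$lon[k] - coast_lon) * mlon +
                        params$eddy_drift_mps * t)
        dy <- (LAT - eddies$lat[k]) * mlat
        psi <- eddies$A[k] * exp(-(dx^2 + dy^2) / (2 * L^2))
        # u = -d(psi*taper)/dy ; v = d(psi*taper)/dx
        u <- u - taper * psi * (-dy / L^2)
        v <- v + taper * psi * (-dx / L^2) + psi * dtaper
      }
    }
    u[!sea] <- 0; v[!sea] <- 0
    list(u = u, v = v, temp = temp_grad(LAT))
  }
  mask <- outer(spec$lon, rep(1, length(spec$lat))) >
    matrix(coast_lon, length(spec$lon), length(spec$lat))
  .eval_on_mesh(spec, fun, mask = mask)
}
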