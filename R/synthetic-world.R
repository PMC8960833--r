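# The default synthetic study world: an idealized Southwest-Atlantic-like
# domain (6N-36S, 53W-24W) with a straight meridional coastline, twelve
# coastal receiving strips, and a synthetic 136-platform inventory grouped
# into 26 clusters across seven oil-producing basins. The platform table is
# a synthetic stand-in (see platforms_synthetic.csv): positions are
# idealized, but the basin-level structure (total platform count, the
# single-platform Camamu site, the heavy concentration of platforms in
# Campos, near-coast northern sites vs offshore southern sites in the eddy
# band) mirrors the real inventory's shape.

#' Default synthetic domain
#'
#' @param dlon,dlat grid spacing (degrees).
#' @param duration_days time-axis length (days).
#' @param frame_seconds field frame spacing (s).
#' @return list with the [grid_spec()] and the coastline longitude.
#' @export
default_domain <- function(dlon = 0.5, dlat = 0.5, duration_days = 90,
                           frame_seconds = 86400) {
  list(spec = grid_spec(c(-53, -24), c(-36, 6), dlon, dlat,
                        duration_days, frame_seconds),
       coast_lon = -50)
}

#' Synthetic platform inventory
#'
#' Builds the synthetic 136-platform table: 26 clusters over seven basins,
#' each cluster a ring of platforms within 3 km of its center (so a 9-km
#' buffer union merges every cluster into one source area and no two
#' clusters merge). Identical to the bundled
#' `extdata/platforms_synthetic.csv`.
#'
#' @return data.frame with id, lon, lat, basin.
#' @export
synthetic_platform_table <- function() {
  clusters <- rbind(
    data.frame(basin = "Ceara",           lat = c(-2.8, -3.1),  lon = -49.30, n = c(4, 4)),
    data.frame(basin = "Potiguar",        lat = c(-4.4, -4.8),  lon = -49.30, n = c(5, 5)),
    data.frame(basin = "Sergipe-Alagoas", lat = c(-10.2, -10.9, -11.6), lon = -49.30, n = c(4, 4, 4)),
    data.frame(basin = "Camamu",          lat = -13.5,          lon = -49.30, n = 1),
    data.frame(basin = "Espirito Santo",  lat = c(-19.0, -19.7, -20.4), lon = -48.80, n = c(6, 5, 5)),
    data.frame(basin = "Campos",          lat = seq(-21.4, -23.2, by = -0.3), lon = -48.40, n = c(9, 9, 9, 8, 8, 8, 8)),
    data.frame(basin = "Santos",          lat = seq(-23.8, -26.6, by = -0.4), lon = -48.10, n = c(4, 4, 4, 4, 4, 4, 3, 3)))
  rows <- list(); pid <- 0L
  for (k in seq_len(nrow(clusters))) {
    nk <- clusters$n[k]
    if (nk == 1) {
      dx <- 0; dy <- 0
    } else {
      ang <- 2 * pi * (seq_len(nk) - 1) / nk
      dx <- 3 * cos(ang); dy <- 3 * sin(ang)   # km ring, radius 3
    }
    lon <- clusters$lon[k] + dx * 1000 / .m_per_deg_lon(clusters$lat[k])
    lat <- clusters$lat[k] + dy * 1000 / .m_per_deg_lat()
    rows[[k]] <- data.frame(
      id = sprintf("P%03d", pid + seq_len(nk)),
      lon = round(lon, 5), lat = round(lat, 5),
      basin = clusters$basin[k], stringsAsFactors = FALSE)
    pid <- pid + nk
  }
  do.call(rbind, rows)
}

#' Default receiving areas of the synthetic world
#'
#' Twelve shelf strips along the idealized coast, labelled with the twelve
#' Brazilian coastal-zone codes south to north; the alongshore breaks are
#' placed so each zone faces its synthetic source basin (e.g. the
#' Sergipe-Alagoas strip spans the Sergipe-Alagoas platform latitudes).
#'
#' @param coast_lon coastline longitude.
#' @param shelf_width_km strip width standing in for the 200-m isobath.
#' @return a `receiving_areas` object.
#' @export
default_receiving_areas <- function(coast_lon = -50, shelf_width_km = 60) {
  breaks <- c(-36, -28, -23.5, -21, -17.5, -12.5, -9, -6.5, -4, -2, 0,
              3, 6)
  build_receiving_areas(breaks, coast_lon, shelf_width_km,
                        ids = c("PEL", "SAN", "CAM", "ES", "BA", "SEAL",
                                "PEPB", "POT", "CE", "BAR", "PAMA",
                                "AM"))
}
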