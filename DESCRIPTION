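Package: larvadrift
Title: Biophysical Larval Dispersal Simulation and Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based Lagrangian simulation of planktonic larval
    dispersal through gridded, time-varying ocean current and temperature
    fields, with fourth-order Runge-Kutta advection, Okubo-scaled turbulent
    random walk, reflecting ("bouncing") coastline behaviour, and mortality
    by advection out of the domain or by lethal temperature. Includes a
    parameterized idealized western-boundary-current generator (seasonally
    migrating bifurcation, mesoscale eddy band, meridional temperature
    gradient) standing in for an ocean hindcast, source-area construction
    from platform coordinates by metric buffer merging, proportional release
    allocation, and the downstream connectivity statistics: mortality by
    advection, larval-supply matrices, source-basin effectiveness, per-km2
    incidence on receiving areas, great-circle path lengths, kernel density
    surfaces, and rank-based seasonal and interannual comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    mgcv,
    MASS,
    rlang,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
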