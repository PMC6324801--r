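# Embedded photon/electron interaction data for the materials of a linac
# treatment head and water phantom.
#
# Channel construction:
#   * compton  : closed-form Klein-Nishina total cross-section per electron,
#                scaled by N_A * Z/A (exact within free-electron approximation)
#   * photoelectric : difference (total - compton) at low-energy anchor nodes
#                of standard total mass-attenuation compilations, extended to
#                high energy by a fitted log-log power law
#   * pair     : difference (total - compton - photoelectric) above the
#                1.022 MeV threshold, floored at a tiny positive value
# Total mass-attenuation anchors are transcribed from standard photon
# cross-section compilations (values in cm^2/g, without renormalisation).
# Rayleigh scattering is not modelled (non-goal): below ~2 MeV the channel
# sums therefore run 2-4% under the anchor totals, which include coherent
# scatter; at therapy energies the difference vanishes.
# Atomic edge structure (tungsten K edge at 69.5 keV) is represented only by
# the anchor nodes themselves; log-log interpolation between nodes smooths it.

ELECTRON_REST_MEV <- 0.511
CLASSICAL_E_RADIUS_CM <- 2.8179403e-13
AVOGADRO <- 6.02214076e23

# shared photon energy grid (MeV)
.photon_energy_grid <- c(
  0.01, 0.015, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.1, 0.15, 0.2,
  0.3, 0.4, 0.5, 0.6, 0.8, 1.0, 1.25, 1.5, 2.0, 3.0, 4.0, 5.0, 6.0,
  8.0, 10.0, 15.0, 20.0
)

# total mass attenuation mu/rho (cm^2/g) at the grid nodes
.total_mu_rho <- list(
  water = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059, 0.1837,
            0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.0969, 0.0896, 0.0786,
            0.0707, 0.0632, 0.0575, 0.0494, 0.0397, 0.0340, 0.0303, 0.0277,
            0.0243, 0.0222, 0.0194, 0.0181),
  air = c(5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875, 0.1662,
          0.1541, 0.1356, 0.1233, 0.1067, 0.0954, 0.0871, 0.0806, 0.0707,
          0.0636, 0.0568, 0.0518, 0.0445, 0.0358, 0.0308, 0.0275, 0.0252,
          0.0223, 0.0204, 0.0181, 0.0170),
  tungsten = c(96.91, 110.0, 65.73, 22.73, 10.67, 5.949, 3.713, 7.810,
               4.438, 1.581, 0.7844, 0.3238, 0.1925, 0.1378, 0.1093, 0.0841,
               0.0662, 0.0594, 0.0546, 0.0438, 0.0405, 0.0402, 0.0409,
               0.0418, 0.0438, 0.0465, 0.0518, 0.0558),
  steel = c(170.6, 57.08, 25.68, 8.176, 3.629, 1.958, 1.205, 0.5952,
            0.3717, 0.1964, 0.1460, 0.1099, 0.0940, 0.0841, 0.0769, 0.0668,
            0.0600, 0.0537, 0.0488, 0.0425, 0.0362, 0.0331, 0.0314, 0.0305,
            0.0296, 0.0294, 0.0297, 0.0305)
)

# Z/A (electrons per atomic mass unit) and bulk density g/cm^3
.material_scalars <- list(
  water    = list(za = 0.55509, density = 1.000),
  air      = list(za = 0.49919, density = 1.205e-3),
  tungsten = list(za = 0.40250, density = 19.30),
  steel    = list(za = 0.46556, density = 8.00)
)

# highest anchor node used to pin the photoelectric channel (below this
# photoelectric is taken as total - compton; above, power-law extension)
.pe_anchor_max <- list(water = 0.06, air = 0.06, tungsten = 0.6, steel = 0.3)

# electron CSDA range tables (energy MeV -> range g/cm^2); water per standard
# stopping-power compilations, others approximate (used only to convert
# distance-expressed production cuts into energies)
.csda_energy <- c(0.01, 0.02, 0.03, 0.05, 0.07, 0.1, 0.15, 0.2, 0.3, 0.4,
                  0.5, 0.7, 1.0, 1.25, 1.5, 2.0, 3.0, 4.0, 5.0, 7.0, 10.0,
                  15.0, 20.0)
.csda_range <- list(
  water = c(2.515e-4, 8.566e-4, 1.756e-3, 4.320e-3, 7.718e-3, 1.431e-2,
            2.817e-2, 4.497e-2, 8.424e-2, 1.280e-1, 1.766e-1, 2.795e-1,
            4.367e-1, 5.610e-1, 7.075e-1, 9.785e-1, 1.514, 2.037, 2.550,
            3.545, 4.975, 7.219, 9.320),
  air = c(2.88e-4, 9.79e-4, 2.00e-3, 4.91e-3, 8.74e-3, 1.62e-2, 3.18e-2,
          5.07e-2, 9.47e-2, 1.44e-1, 1.98e-1, 3.13e-1, 4.89e-1, 6.28e-1,
          7.92e-1, 1.096, 1.695, 2.281, 2.856, 3.970, 5.572, 8.085, 10.44),
  tungsten = c(4.4e-4, 1.45e-3, 2.9e-3, 7.0e-3, 1.23e-2, 2.25e-2, 4.35e-2,
               6.85e-2, 1.26e-1, 1.90e-1, 2.60e-1, 4.05e-1, 6.30e-1,
               8.20e-1, 1.015, 1.41, 2.19, 2.95, 3.68, 5.08, 7.05, 10.0,
               12.7),
  steel = c(3.0e-4, 1.02e-3, 2.08e-3, 5.10e-3, 9.10e-3, 1.68e-2, 3.30e-2,
            5.25e-2, 9.80e-2, 1.49e-1, 2.05e-1, 3.24e-1, 5.06e-1, 6.50e-1,
            8.20e-1, 1.133, 1.752, 2.357, 2.952, 4.104, 5.760, 8.357, 10.79)
)

#' Klein-Nishina total cross-section
#'
#' Total Compton cross-section per free electron at a given photon energy,
#' from the closed-form integral of the Klein-Nishina differential
#' cross-section.
#'
#' @param energy Photon energy in MeV (vectorised).
#' @return Cross-section in cm^2 per electron.
#' @keywords internal
klein_nishina_total <- function(energy) {
  a <- energy / ELECTRON_REST_MEV
  l <- log(1 + 2 * a)
  2 * pi * CLASSICAL_E_RADIUS_CM^2 * (
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - l / a) +
      l / (2 * a) - (1 + 3 * a) / (1 + 2 * a)^2
  )
}

# mean fraction of photon energy given to the Compton electron, by numerical
# quadrature of the Klein-Nishina differential cross-section in the scattered
# fraction eps = E'/E
.kn_electron_fraction <- function(energy) {
  vapply(energy, function(E) {
    a <- E / ELECTRON_REST_MEV
    lo <- 1 / (1 + 2 * a)
    eps <- seq(lo, 1, length.out = 2001)
    # dsigma/deps ~ eps + 1/eps - sin^2(theta), with the Compton relation
    # cos(theta) = 1 - (1/eps - 1)/a
    cth <- 1 - (1 / eps - 1) / a
    w <- eps + 1 / eps - (1 - cth^2)
    mean_eps <- sum(w * eps) / sum(w)
    1 - mean_eps
  }, numeric(1))
}

.build_material <- function(name) {
  sc <- .material_scalars[[name]]
  E <- .photon_energy_grid
  total <- .total_mu_rho[[name]]
  compton <- AVOGADRO * sc$za * klein_nishina_total(E)
  # photoelectric: pinned below the anchor cut, power-law extended above
  cut <- .pe_anchor_max[[name]]
  anchor <- E <= cut + 1e-12
  pe <- pmax(total - compton, 1e-12)
  ia <- which(anchor)
  # fit slope on the last two anchor nodes, clamp to a physical range
  i1 <- ia[length(ia) - 1]; i2 <- ia[length(ia)]
  slope <- (log(pe[i2]) - log(pe[i1])) / (log(E[i2]) - log(E[i1]))
  slope <- max(min(slope, -1), -3.5)
  ext <- !anchor
  pe[ext] <- pe[i2] * (E[ext] / E[i2])^slope
  pe <- pmax(pe, 1e-12)
  # pair production above threshold
  pair <- rep(1e-12, length(E))
  above <- E > 2 * ELECTRON_REST_MEV
  pair[above] <- pmax(total[above] - compton[above] - pe[above], 1e-12)
  structure(
    list(
      name = name,
      density = sc$density,
      za = sc$za,
      attenuation_table = tibble::tibble(
        energy = E,
        photoelectric = pe,
        compton = compton,
        pair = pair,
        total = pe + compton + pair
      ),
      csda_table = tibble::tibble(
        energy = .csda_energy,
        range = .csda_range[[name]]
      ),
      electron_fraction = .kn_electron_fraction(E)
    ),
    class = "linac_material"
  )
}

.materials_cache <- new.env(parent = emptyenv())

#' Material data for head and phantom media
#'
#' Returns the embedded interaction data for one of the materials used by the
#' beam model: `"water"`, `"air"`, `"tungsten"` (target and jaws) or
#' `"steel"` (flattening-filter alloy).
#'
#' @param name Material name.
#' @return An object of class `linac_material`: a list with the bulk
#'   `density` (g/cm^3), the per-channel mass attenuation table
#'   (`attenuation_table`, cm^2/g) and the electron CSDA range table
#'   (`csda_table`, g/cm^2).
#' @examples
#' w <- linac_material("water")
#' head(w$attenuation_table)
#' @export
linac_material <- function(name = c("water", "air", "tungsten", "steel")) {
  name <- match.arg(name)
  if (is.null(.materials_cache[[name]])) {
    assign(name, .build_material(name), envir = .materials_cache)
  }
  .materials_cache[[name]]
}

#' @export
print.linac_material <- function(x, ...) {
  cat("<linac_material> ", x$name, "  density ", x$density, " g/cm^3\n",
      sep = "")
  cat("  attenuation nodes: ", nrow(x$attenuation_table),
      " over [", min(x$attenuation_table$energy), ", ",
      max(x$attenuation_table$energy), "] MeV\n", sep = "")
  invisible(x)
}

.as_material <- function(material) {
  if (inherits(material, "linac_material")) return(material)
  linac_material(material)
}

#' Linear attenuation coefficient
#'
#' Log-log interpolation of the embedded mass-attenuation table, multiplied
#' by the bulk density.
#'
#' @param material A `linac_material` or material name.
#' @param energy Photon energy in MeV (vectorised); must lie within the
#'   tabulated range 0.01-20 MeV.
#' @param channel Interaction channel: `"total"`, `"photoelectric"`,
#'   `"compton"` or `"pair"`.
#' @return Linear attenuation coefficient in 1/cm.
#' @examples
#' attenuation_coefficient("water", 2.0)
#' @export
attenuation_coefficient <- function(material, energy,
                                    channel = c("total", "photoelectric",
                                                "compton", "pair")) {
  channel <- match.arg(channel)
  m <- .as_material(material)
  tab <- m$attenuation_table
  rng <- range(tab$energy)
  if (any(energy < rng[1] - 1e-12 | energy > rng[2] + 1e-12)) {
    stop("energy outside tabulated range [", rng[1], ", ", rng[2], "] MeV",
         call. = FALSE)
  }
  mu <- exp(stats::approx(log(tab$energy), log(tab[[channel]]),
                          xout = log(energy), rule = 2)$y)
  mu * m$density
}

#' Convert a distance-expressed production cut to a threshold energy
#'
#' Inverts the embedded CSDA-range table for a material: the threshold is the
#' smallest tabulated electron energy whose CSDA range (converted to a
#' distance through the bulk density) is at least the requested cut.
#' Particles below the threshold are terminated with local energy deposit.
#'
#' @param material A `linac_material` or material name.
#' @param range_cut Cut expressed as a distance in mm (default 1 mm, the
#'   conventional production threshold). A zero cut returns the lowest
#'   tabulated energy.
#' @return Threshold kinetic energy in MeV.
#' @examples
#' range_cut_to_energy("water", 1)
#' @export
range_cut_to_energy <- function(material, range_cut = 1) {
  m <- .as_material(material)
  if (range_cut < 0) stop("range_cut must be non-negative", call. = FALSE)
  tab <- m$csda_table
  if (range_cut == 0) return(tab$energy[1])
  cut_gcm2 <- (range_cut / 10) * m$density
  ok <- which(tab$range >= cut_gcm2)
  if (!length(ok)) {
    stop("range_cut ", range_cut, " mm beyond tabulated CSDA range for ",
         m$name, call. = FALSE)
  }
  tab$energy[ok[1]]
}

# water collision stopping power (MeV/cm) from the CSDA table by midpoint
# finite differences, on a log energy grid; used by the condensed-history
# electron stepper
.stopping_power_table <- function(material) {
  m <- .as_material(material)
  tab <- m$csda_table
  E <- tab$energy
  R <- tab$range / m$density  # cm at bulk density
  mid_E <- sqrt(E[-1] * E[-length(E)])
  S <- diff(E) / diff(R)  # MeV per cm
  tibble::tibble(energy = mid_E, stopping = S)
}

# energy-transfer coefficient table for water (1/cm): weights each channel by
# the mean fraction of photon energy handed to charged particles; used by the
# collision-kerma track-length estimator
.mu_tr_table <- function(material = "water") {
  m <- .as_material(material)
  tab <- m$attenuation_table
  f_pair <- pmax(tab$energy - 2 * ELECTRON_REST_MEV, 0) / tab$energy
  mu_tr <- (tab$photoelectric + tab$compton * m$electron_fraction +
              tab$pair * f_pair) * m$density
  tibble::tibble(energy = tab$energy, mu_tr = mu_tr)
}
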