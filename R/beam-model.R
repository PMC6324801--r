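# Parameterised electron source and treatment head.
#
# Geometry convention: z increases from the target (z = 0) toward the phantom
# surface (z = 100 cm, the SSD); all lengths in cm unless a field name says mm.

#' Primary electron source configuration
#'
#' @param mean_energy Mean kinetic energy of the primary electron beam (MeV).
#' @param energy_spread_sigma Gaussian energy spread (standard deviation, MeV).
#' @param spot_fwhm_mm Full width at half maximum of the isotropic 2-D
#'   Gaussian focal spot (mm).
#' @return A `source_config` object.
#' @examples
#' fff7mv_source()
#' @export
source_config <- function(mean_energy, energy_spread_sigma = 0.4,
                          spot_fwhm_mm = 1) {
  stopifnot(mean_energy > 0, energy_spread_sigma >= 0, spot_fwhm_mm > 0)
  structure(
    list(mean_energy = mean_energy,
         energy_spread_sigma = energy_spread_sigma,
         spot_fwhm_mm = spot_fwhm_mm,
         direction = c(0, 0, 1)),
    class = "source_config"
  )
}

#' @rdname source_config
#' @details `fff7mv_source()` and `flat6mv_source()` return the commissioned
#'   source parameters of the two beam lines: 8.8 MeV (FFF 7 MV) and 7.5 MeV
#'   (flattened 6 MV) mean energy, both with 0.4 MeV spread and 1 mm spot.
#' @export
fff7mv_source <- function() source_config(8.8, 0.4, 1)

#' @rdname source_config
#' @export
flat6mv_source <- function() source_config(7.5, 0.4, 1)

#' Treatment-head configuration
#'
#' Parameterises the simplified treatment head: tungsten target, conical
#' primary collimator, optional flattening filter, square jaws, and the
#' source-to-surface drift. The field size is defined at the phantom surface
#' (SSD 100 cm); the jaw half-aperture scales as `field/2 * z_jaw / ssd`.
#'
#' @param mode `"flat"` (filter in beam) or `"fff"` (filter removed).
#' @param field_cm Side of the square field at the surface plane (cm).
#' @param filter_profile For flat mode, a data frame with columns `radius_mm`
#'   and `thickness_mm` describing the filter; `NULL` requests the designed
#'   default profile (see [design_flattening_filter()]).
#' @param target_thickness_mm Tungsten target thickness (mm).
#' @param pc_half_angle Primary-collimator cone half-opening (rad).
#' @param ssd Source-to-surface distance (cm).
#' @param psf_plane_z Phase-space capture plane, above the jaws (cm).
#' @return A `head_config` object.
#' @examples
#' fff7mv_head(10)
#' @export
head_config <- function(mode = c("fff", "flat"), field_cm = 10,
                        filter_profile = NULL,
                        target_thickness_mm = 1,
                        pc_half_angle = 0.28,
                        ssd = 100,
                        psf_plane_z = 25) {
  mode <- match.arg(mode)
  stopifnot(field_cm > 0, ssd > 0)
  if (mode == "fff" && !is.null(filter_profile)) {
    stop("an FFF head cannot carry a flattening filter", call. = FALSE)
  }
  z_jaw <- 30
  structure(
    list(mode = mode,
         field_cm = field_cm,
         target = list(material = "tungsten",
                       thickness_mm = target_thickness_mm, z_cm = 0),
         primary_collimator = list(half_angle = pc_half_angle,
                                   material = "tungsten", z_exit = 10),
         filter_z = 12,
         filter_profile = filter_profile,
         jaws = list(material = "tungsten", z_cm = z_jaw,
                     half_aperture_cm = field_cm / 2 * z_jaw / ssd),
         ssd = ssd,
         psf_plane_z = psf_plane_z),
    class = "head_config"
  )
}

#' @export
print.head_config <- function(x, ...) {
  cat("<head_config> mode=", x$mode, " field=", x$field_cm, "x",
      x$field_cm, " cm at SSD ", x$ssd, "\n", sep = "")
  if (!is.null(x$filter_profile)) {
    cat("  filter: ", nrow(x$filter_profile), " radial nodes, t(0)=",
        round(x$filter_profile$thickness_mm[1], 1), " mm\n", sep = "")
  }
  invisible(x)
}

#' @export
print.source_config <- function(x, ...) {
  cat("<source_config> E=", x$mean_energy, " MeV, sigma=",
      x$energy_spread_sigma, " MeV, spot FWHM=", x$spot_fwhm_mm, " mm\n",
      sep = "")
  invisible(x)
}

.head_cache <- new.env(parent = emptyenv())

#' @rdname head_config
#' @details `fff7mv_head()` and `flat6mv_head()` build the two preset heads.
#'   The flattened head uses the filter designed once per session by
#'   [design_flattening_filter()] at its defaults (cached).
#' @export
fff7mv_head <- function(field_cm = 10) head_config("fff", field_cm)

#' @rdname head_config
#' @export
flat6mv_head <- function(field_cm = 10, filter_profile = NULL) {
  if (is.null(filter_profile)) {
    if (is.null(.head_cache$filter)) {
      .head_cache$filter <- design_flattening_filter()
    }
    filter_profile <- .head_cache$filter
  }
  head_config("flat", field_cm, filter_profile = filter_profile)
}

# derived bremsstrahlung-source parameters for a (source, head) pair
.brems_params <- function(source, head) {
  t_cm <- head$target$thickness_mm / 10
  w <- linac_material("tungsten")
  sp <- .stopping_power_table("tungsten")
  S_w <- stats::approx(sp$energy, sp$stopping, xout = source$mean_energy,
                       rule = 2)$y
  delta_half <- 0.5 * S_w * t_cm
  e_eff <- source$mean_energy - delta_half
  thetac <- ELECTRON_REST_MEV / (e_eff + ELECTRON_REST_MEV)
  # Highland tilt through the full target (X0 tungsten = 6.76 g/cm^2)
  X0_cm <- 6.76 / w$density
  pc <- sqrt(e_eff * (e_eff + 2 * ELECTRON_REST_MEV))
  pbeta <- pc^2 / (e_eff + ELECTRON_REST_MEV)
  xr <- t_cm / X0_cm
  theta0 <- 13.6 / pbeta * sqrt(xr) * max(1 + 0.038 * log(xr), 0.25)
  kmin <- 0.05
  k_grid <- exp(seq(log(kmin), log(20), length.out = 60))
  mu_w <- attenuation_coefficient("tungsten", k_grid)
  m <- mu_w * t_cm
  tbar <- (1 - exp(-m)) / m
  # photon number per primary from the classical thick-target radiative yield
  yield <- 6e-4 * 74 * source$mean_energy / (1 + 6e-4 * 74 * source$mean_energy)
  kk <- seq(kmin, e_eff, length.out = 2000)
  B <- 1 - kk / e_eff + 0.75 * (kk / e_eff)^2
  e_bar <- sum(B) / sum(B / kk)   # intensity-weighted mean emitted energy
  n_tot <- yield * source$mean_energy / e_bar
  list(kmin = kmin, delta_half = delta_half, theta0 = theta0,
       thetac = thetac, k_grid = k_grid, tbar = tbar, n_tot_mean = n_tot,
       e_eff = e_eff)
}

#' Sample primary electrons
#'
#' Draws primary-electron states from the source model: kinetic energy from a
#' truncated Gaussian, transverse position from an isotropic 2-D Gaussian
#' with `sigma = FWHM / (2 sqrt(2 log 2))`, direction fixed along +z.
#'
#' @param n Number of electrons.
#' @param source A [source_config()].
#' @return A tibble of particle states (kind, energy, x/y/z in mm, direction
#'   cosines, weight).
#' @export
sample_primary_electron <- function(n, source) {
  sigma_mm <- source$spot_fwhm_mm / (2 * sqrt(2 * log(2)))
  e <- stats::rnorm(n, source$mean_energy, source$energy_spread_sigma)
  while (any(bad <- e <= 0)) {
    e[bad] <- stats::rnorm(sum(bad), source$mean_energy,
                           source$energy_spread_sigma)
  }
  tibble::tibble(
    kind = "electron",
    energy = e,
    x_mm = stats::rnorm(n, 0, sigma_mm),
    y_mm = stats::rnorm(n, 0, sigma_mm),
    z_mm = 0,
    u = 0, v = 0, w = 1,
    weight = 1
  )
}

#' Design a flattening filter for the flattened beam line
#'
#' Constructs the radial thickness profile `t(r)` of a conical steel filter
#' such that the energy-fluence-weighted transmitted intensity at the phantom
#' surface is uniform over 80% of the reference field. The unfiltered radial
#' intensity comes from the head's composite angular model (multiple
#' scattering in the target convolved with the intrinsic bremsstrahlung
#' angle); the spectral transmission integral is inverted radius by radius
#' with a monotone root bracketing.
#'
#' @param source Source used for the flattened line (defaults to
#'   [flat6mv_source()]).
#' @param head A template head (geometry only; its mode is ignored).
#' @param reference_field Field side (cm) over which the beam is flattened.
#' @param flatness_tolerance Permitted relative ripple of the designed
#'   transmitted intensity over 80% of the reference field.
#' @param fluence_profile Optional override for the unfiltered radial
#'   intensity: a function of the polar angle (rad) returning relative
#'   intensity. Used mainly for testing.
#' @return A filter profile tibble (`radius_mm`, `thickness_mm`) with
#'   non-increasing thickness, carrying the design residual as an attribute.
#' @export
design_flattening_filter <- function(source = flat6mv_source(),
                                     head = head_config("fff"),
                                     reference_field = 40,
                                     flatness_tolerance = 0.02,
                                     fluence_profile = NULL) {
  bp <- .brems_params(source, head)
  ssd <- head$ssd
  if (is.null(fluence_profile)) {
    at <- cpp_angular_table(bp$theta0, bp$thetac)
    fluence_profile <- function(theta) {
      stats::approx(at$theta, at$intensity, xout = theta, rule = 2)$y
    }
  }
  # emission spectrum (photon number density) after target self-attenuation
  kk <- seq(bp$kmin, bp$e_eff, length.out = 400)
  B <- 1 - kk / bp$e_eff + 0.75 * (kk / bp$e_eff)^2
  tb <- stats::approx(log(bp$k_grid), bp$tbar, xout = log(kk), rule = 2)$y
  nk <- B / kk * tb
  mu_f <- attenuation_coefficient("steel", kk)
  z_f <- head$filter_z
  r_flat <- 0.8 * reference_field / 2        # flattened radius at the surface
  r_surf <- seq(0, r_flat, length.out = 41)
  theta <- atan(r_surf / ssd)
  # energy fluence per unit surface area (inverse-square and obliquity fold
  # out as cos^3)
  psi0 <- fluence_profile(theta) * cos(theta)^3 * sum(nk * kk)
  target_level <- psi0[length(psi0)]         # flatten down to the edge value
  trans <- function(t_cm, cth) sum(nk * kk * exp(-mu_f * t_cm / cth)) /
    sum(nk * kk)
  t_r <- vapply(seq_along(r_surf), function(i) {
    need <- target_level / psi0[i]
    if (need >= 1) return(0)
    f <- function(t) trans(t, cos(theta[i])) - need
    stats::uniroot(f, c(0, 30), tol = 1e-6)$root
  }, numeric(1))
  # enforce the monotone (non-increasing) physical shape
  t_r <- rev(cummax(rev(t_r)))
  # verify the design in closed loop against the model
  resid <- vapply(seq_along(r_surf), function(i) {
    psi0[i] * trans(t_r[i], cos(theta[i])) / target_level - 1
  }, numeric(1))
  if (max(abs(resid)) > flatness_tolerance) {
    stop("flattening-filter design did not converge: max residual ",
         signif(max(abs(resid)), 3), " over 80% of the reference field",
         call. = FALSE)
  }
  out <- tibble::tibble(
    radius_mm = r_surf * z_f / ssd * 10,
    thickness_mm = t_r * 10
  )
  attr(out, "residual") <- resid
  attr(out, "material") <- "steel"
  class(out) <- c("filter_profile", class(out))
  out
}

#' Transmit particles through the treatment head
#'
#' Runs the head stage only (collimator, optional filter, jaws, air column)
#' for an externally supplied particle set and returns the survivors at the
#' phantom surface plane. Electrons in the input are treated as head
#' contaminant electrons.
#'
#' @param particles Tibble as returned by [sample_primary_electron()] but
#'   with `kind` `"photon"`/`"electron"`, positions in mm and `z_mm` giving
#'   the starting plane.
#' @param head A [head_config()].
#' @param source Source used only for the bremsstrahlung model constants.
#' @param air Logical: sample interactions in the air column.
#' @return Tibble of surviving particles at z = SSD.
#' @export
transmit_through_head <- function(particles, head, source = fff7mv_source(),
                                  air = TRUE) {
  model <- .engine_model(head, source,
                         run_config(n_histories = 1, batches = 1,
                                    air_interactions = air),
                         scoring_off())
  kind_num <- ifelse(particles$kind == "photon", 0, 1)
  m <- cbind(kind_num, particles$energy,
             particles$x_mm / 10, particles$y_mm / 10, particles$z_mm / 10,
             particles$u, particles$v, particles$w, particles$weight)
  res <- cpp_head_transmit(m, model)
  tibble::tibble(
    kind = ifelse(res[, 1] == 0, "photon",
                  ifelse(res[, 1] == 1, "electron", "positron")),
    energy = res[, 2],
    x_mm = res[, 3] * 10, y_mm = res[, 4] * 10, z_mm = head$ssd * 10,
    u = res[, 5], v = res[, 6], w = res[, 7],
    weight = res[, 8]
  )
}

#' Read a beam configuration from YAML
#'
#' Loads a head + source preset of the schema shipped in
#' `inst/extdata/fff7mv.yaml` and `inst/extdata/flat6mv.yaml`.
#'
#' @param path YAML file path, or one of the preset names `"fff7mv"`,
#'   `"flat6mv"`.
#' @param field_cm Optional field-size override (cm).
#' @return A list with elements `head` and `source`.
#' @export
read_beam_config <- function(path, field_cm = NULL) {
  if (path %in% c("fff7mv", "flat6mv")) {
    path <- system.file("extdata", paste0(path, ".yaml"), package = "linacmc")
  }
  cfg <- yaml::read_yaml(path)
  src <- source_config(cfg$source$mean_energy,
                       cfg$source$energy_spread_sigma,
                       cfg$source$spot_fwhm_mm)
  fc <- field_cm %||% cfg$head$field_cm
  if (identical(cfg$head$mode, "flat")) {
    head <- flat6mv_head(fc)
  } else {
    head <- head_config("fff", fc,
                        target_thickness_mm = cfg$head$target_thickness_mm %||% 1)
  }
  list(head = head, source = src)
}
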