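# Synthetic water-tank reference scans: analytic depth-dose and profile
# models with the statistical structure of chamber scans (1 mm steps,
# additive Gaussian noise), plus the simulator-as-reference harness.

#' Synthetic beam model
#'
#' Analytic scan model emulating water-tank measurements: the depth dose is
#' buildup times exponential falloff times inverse square,
#' `D(z) = (1 - exp(-b z)) exp(-mu z) (SSD/(SSD+z))^2`, with `b` solved so
#' the maximum falls at `dmax_mm`; profiles are a flat top (flat mode) or a
#' linear cone `1 + cone_per_mm |x|` (FFF), times error-function penumbrae
#' of slope `penumbra_sigma_mm`, times a linear asymmetry factor.
#'
#' @param mode `"fff"` or `"flat"` (sets dmax and effective attenuation
#'   defaults: 19 mm / 0.0358 cm^-1 for FFF, 16 mm / 0.0373 cm^-1 for the
#'   flattened line, matching the penetration of the two beams).
#' @param field_mm Field size at the surface (mm).
#' @param dmax_mm Depth of maximum dose (mm).
#' @param mu_eff_cm Effective exponential attenuation (1/cm).
#' @param penumbra_sigma_mm Error-function edge scale (mm); the 20-80%
#'   penumbra equals `2 qnorm(0.8) sigma = 1.683 sigma`.
#' @param cone_per_mm FFF cone coefficient (relative increase per mm toward
#'   the axis); ignored for flat mode.
#' @param asymmetry Linear asymmetry factor per mm.
#' @param noise_pct Additive Gaussian noise, % of the curve maximum.
#' @param step_mm Scan step (mm), 1 mm by convention.
#' @param ssd Source-to-surface distance (cm).
#' @return A `synthetic_beam_model` object.
#' @export
synthetic_beam_model <- function(mode = c("fff", "flat"), field_mm = 100,
                                 dmax_mm = NULL, mu_eff_cm = NULL,
                                 penumbra_sigma_mm = 5.5,
                                 cone_per_mm = 0.003,
                                 asymmetry = 0, noise_pct = 0.3,
                                 step_mm = 1, ssd = 100) {
  mode <- match.arg(mode)
  dmax_mm <- dmax_mm %||% if (mode == "fff") 19 else 16
  mu_eff_cm <- mu_eff_cm %||% if (mode == "fff") 0.0358 else 0.0373
  stopifnot(field_mm > 0, dmax_mm > 0, mu_eff_cm > 0,
            penumbra_sigma_mm > 0, noise_pct >= 0, step_mm > 0)
  # buildup rate solved so d/dz[(1-e^{-bz}) e^{-cz} invsq] = 0 at dmax
  c_mm <- mu_eff_cm / 10 + 2 / (ssd * 10 + dmax_mm)
  f <- function(b) b * exp(-b * dmax_mm) / (1 - exp(-b * dmax_mm)) - c_mm
  b <- stats::uniroot(f, c(1e-4, 2))$root
  structure(
    list(mode = mode, field_mm = field_mm, dmax_mm = dmax_mm,
         mu_eff_cm = mu_eff_cm, buildup_b = b,
         penumbra_sigma_mm = penumbra_sigma_mm,
         cone_per_mm = if (mode == "fff") cone_per_mm else 0,
         asymmetry = asymmetry, noise_pct = noise_pct,
         step_mm = step_mm, ssd = ssd),
    class = "synthetic_beam_model"
  )
}

.synthetic_pdd_fn <- function(model) {
  function(z_mm) {
    (1 - exp(-model$buildup_b * z_mm)) *
      exp(-model$mu_eff_cm * z_mm / 10) *
      (model$ssd / (model$ssd + z_mm / 10))^2
  }
}

.synthetic_profile_fn <- function(model) {
  s <- model$penumbra_sigma_mm
  L <- model$field_mm
  function(x_mm) {
    core <- 1 + model$cone_per_mm * pmax(0, L / 2 - abs(x_mm)) *
      (model$mode == "fff")
    # edges expressed with the cumulative normal (erf rescaled)
    edge <- (stats::pnorm((x_mm + L / 2) / s) -
               stats::pnorm((x_mm - L / 2) / s))
    core * edge * (1 + model$asymmetry * x_mm)
  }
}

#' Generate synthetic reference scans
#'
#' Deterministic per seed: a depth-dose curve (0-300 mm) and profiles at
#' dmax and 10 cm depth, sampled at the model's scan step with additive
#' Gaussian noise, in the reference CSV-compatible [scan_curve()] form.
#'
#' @param model A [synthetic_beam_model()].
#' @param seed Seed for the noise.
#' @return List with `pdd`, `profile` (10 cm depth), `profile_dmax`, and
#'   the generating `model`.
#' @export
generate_reference <- function(model, seed = 1) {
  set.seed(seed)
  z <- seq(0.5, 300, by = model$step_mm)
  pdd_v <- .synthetic_pdd_fn(model)(z)
  pdd_v <- 100 * pdd_v / max(pdd_v)
  pdd_v <- pdd_v + stats::rnorm(length(z), 0, model$noise_pct)
  x <- seq(-model$field_mm, model$field_mm, by = model$step_mm)
  pf <- .synthetic_profile_fn(model)
  prof_v <- 100 * pf(x) / pf(0)
  prof10 <- prof_v + stats::rnorm(length(x), 0, model$noise_pct)
  profdm <- prof_v * (1 + 0.0) +
    stats::rnorm(length(x), 0, model$noise_pct)
  list(
    pdd = scan_curve(z, pmax(pdd_v, 0), kind = "pdd",
                     normalization = "dmax"),
    profile = scan_curve(x, pmax(prof10, 0), kind = "profile",
                         normalization = "cax",
                         meta = list(depth_cm = 10)),
    profile_dmax = scan_curve(x, pmax(profdm, 0), kind = "profile",
                              normalization = "cax",
                              meta = list(depth_cm = model$dmax_mm / 10)),
    model = model
  )
}

#' Use the simulator itself as tuning reference
#'
#' Runs the full simulator at the given configuration and exports its
#' depth-dose and 10 cm profile in the reference-curve dialect, for
#' parameter-recovery (self-consistency) studies.
#'
#' @param head A [head_config()].
#' @param source The "true" [source_config()] to be recovered.
#' @param run A [run_config()] (its seed should differ from the tuning
#'   seed).
#' @param scoring Scoring spec; defaults to the kerma tally used by
#'   [tune_source()].
#' @param dir Optional directory: when given, curves are also written as
#'   CSV (`reference_pdd.csv`, `reference_profile.csv`).
#' @return List with `pdd` and `profile` scan curves.
#' @export
simulator_as_reference <- function(head, source, run, scoring = NULL,
                                   dir = NULL) {
  scoring <- scoring %||% scoring_kerma()
  sim <- run_simulation(head, source, run, scoring)
  out <- list(pdd = sim$cax_pdd, profile = .tuning_profile(sim),
              run = sim)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_scan_curve(out$pdd, file.path(dir, "reference_pdd.csv"))
    write_scan_curve(out$profile, file.path(dir, "reference_profile.csv"))
  }
  out
}
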