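# Shared simulation cache: the heavier Monte-Carlo runs are computed once per
# test session and reused across test files.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.sim_cache[[name]])) {
    assign(name, force(expr), envir = .sim_cache)
  }
  .sim_cache[[name]]
}

# paired full/kill contamination runs (analog, 1 mm cylinder tally)
cc_run <- function(mode, field) {
  cached(paste0("cc_", mode, field), {
    head <- if (mode == "fff") fff7mv_head(field) else flat6mv_head(field)
    src <- if (mode == "fff") fff7mv_source() else flat6mv_source()
    contamination_fraction(head, src,
                           run_config(4e7, seed = 501, batches = 4))
  })
}

# kerma-tally characterisation runs
kerma_run <- function(mode, field, n = 2e7, seed = 601, xhalf = 15) {
  cached(paste0("kerma_", mode, field, "_", n), {
    head <- if (mode == "fff") fff7mv_head(field) else flat6mv_head(field)
    src <- if (mode == "fff") fff7mv_source() else flat6mv_source()
    run_simulation(head, src, run_config(n, seed = seed, batches = 4),
                   scoring_kerma(profile_xhalf_cm = xhalf))
  })
}

# lightweight tuning reference for interface tests
acc_reference <- function() {
  cached("acc_reference", {
    simulator_as_reference(fff7mv_head(10), fff7mv_source(),
                           run_config(4e7, seed = 101, batches = 2))
  })
}

# high-statistics reference shared by the recovery and validation studies
# (reference noise acts like a systematic energy shift on the weakly
# energy-dependent depth-dose statistic, so the reference must be much
# better determined than the grid evaluations)
val_scoring <- function() scoring_kerma(profile_halfthick_cm = 3,
                                        profile_axes = c("x", "y"))

val_reference <- function() {
  cached("val_reference", {
    simulator_as_reference(fff7mv_head(10), fff7mv_source(),
                           run_config(4.5e8, seed = 1211, batches = 2),
                           scoring = val_scoring())
  })
}

acc_tuning <- function() {
  cached("acc_tuning", {
    g <- tuning_grid("fff", mean_energies = seq(8.0, 9.6, 0.4),
                     spreads = c(0.3, 0.5), fwhms = c(1, 2))
    tune_source(fff7mv_head(10), g, val_reference(),
                histories_per_point = 2.56e7, histories_stage2 = 6.4e6,
                seed = 1, scoring = val_scoring())
  })
}

# analytic noiseless FFF reference profile fixture
analytic_fff_profile <- function(noise = 0, seed = 1) {
  generate_reference(synthetic_beam_model("fff", noise_pct = noise),
                     seed = seed)
}

# flat-top profile with error-function edges on a 1 mm grid, cax-normalized
flat_erf_profile <- function(field_mm = 100, sigma_mm = 5.5, step_mm = 1) {
  x <- seq(-field_mm, field_mm, by = step_mm)
  d <- 100 * (stats::pnorm((x + field_mm / 2) / sigma_mm) -
                stats::pnorm((x - field_mm / 2) / sigma_mm))
  scan_curve(x, d, kind = "profile", normalization = "cax")
}

# triangular FFF-like cone with linear flanks (exact slope/peak fixtures)
triangle_profile <- function(g_per_mm = 0.3, half_mm = 50, shift_mm = 0,
                             sigma_mm = 4, step_mm = 1) {
  x <- seq(-2 * half_mm, 2 * half_mm, by = step_mm)
  core <- 100 - g_per_mm * abs(x - shift_mm)
  edge <- stats::pnorm((x - shift_mm + half_mm) / sigma_mm) -
    stats::pnorm((x - shift_mm - half_mm) / sigma_mm)
  scan_curve(x, core * edge, kind = "profile", normalization = "cax")
}
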