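# Monte-Carlo run driver: configuration records, engine-model assembly, and
# the batch loop with reproducible child random streams.

#' Run configuration
#'
#' @param n_histories Number of primary-electron histories (total over all
#'   batches).
#' @param seed Master seed; per-batch child streams are derived from it by a
#'   fixed scheme, so equal seeds give bitwise-identical results.
#' @param kill_electrons_above_phantom Discard any electron/positron crossing
#'   the phantom entrance plane from above (the electron-kill contrast used
#'   to isolate contaminant-electron dose); photons are untouched.
#' @param cut_range_mm Distance-expressed range cut (production/termination
#'   threshold), converted per material via [range_cut_to_energy()].
#' @param batches Number of statistically independent batches kept for the
#'   uncertainty estimate.
#' @param psf_capture Record particles crossing the phase-space plane.
#' @param recycle_factor When the particle source is a [new_phase_space()] object,
#'   how many times each record is reused (with azimuthal re-randomisation).
#' @param air_interactions Sample photon interactions in the air column.
#' @return A `run_config` object.
#' @export
run_config <- function(n_histories = 1e5, seed = 1,
                       kill_electrons_above_phantom = FALSE,
                       cut_range_mm = 1, batches = 10,
                       psf_capture = FALSE, recycle_factor = 1,
                       air_interactions = TRUE) {
  stopifnot(n_histories >= batches, cut_range_mm > 0, batches >= 1)
  structure(
    list(n_histories = n_histories, seed = seed,
         kill_electrons_above_phantom = kill_electrons_above_phantom,
         cut_range_mm = cut_range_mm, batches = batches,
         psf_capture = psf_capture, recycle_factor = recycle_factor,
         air_interactions = air_interactions),
    class = "run_config"
  )
}

# ---------------------------------------------------------------------------
# scoring specifications

.empty_planes <- function() matrix(numeric(0), ncol = 4,
                                   dimnames = list(NULL,
                                     c("z", "xc", "yc", "hw")))

#' Scoring specifications
#'
#' `scoring_grid()` scores analog dose on a voxel grid (5 mm over the full
#' 40x40x40 cm phantom by default, or 1 mm over a restricted region for
#' surface/buildup work), plus an optional central-axis cylindrical tally.
#' `scoring_kerma()` replaces analog electron transport by a collision-kerma
#' track-length estimator on a CAX cylinder (depth-dose) and lateral slab
#' (profile) — the low-variance tally used for source tuning.
#' `scoring_off()` scores nothing (head-only studies and spectra).
#'
#' @param voxel_mm Voxel edge (5 or 1 mm are the conventional choices).
#' @param half_extent_cm Lateral half-extent of the scored region (cm).
#' @param depth_cm Scored depth (cm).
#' @param center Lateral center (x, y) of the scored region (cm).
#' @param cyl_radius_cm Radius of the cylindrical CAX tally; `NULL` disables.
#' @param cyl_offset Lateral offset (x, y) of the cylinder axis (cm), for
#'   off-axis depth-dose columns.
#' @param cyl_dz_mm Depth resolution of the cylinder tally (mm).
#' @param planes Spectral scoring planes: matrix/data frame with columns
#'   `z`, `xc`, `yc`, `hw` (cm); see [surface_plane()].
#' @return A `scoring_spec` object.
#' @export
scoring_grid <- function(voxel_mm = 5, half_extent_cm = 20, depth_cm = 40,
                         center = c(0, 0), cyl_radius_cm = 1,
                         cyl_offset = c(0, 0), cyl_dz_mm = voxel_mm,
                         planes = NULL) {
  d <- voxel_mm / 10
  n_lat <- max(1L, as.integer(round(2 * half_extent_cm / d)))
  n_z <- max(1L, as.integer(round(depth_cm / d)))
  structure(
    list(kerma_mode = FALSE,
         grid_on = TRUE,
         gx0 = center[1] - half_extent_cm, gy0 = center[2] - half_extent_cm,
         gz0 = 100, gd = d, gnx = n_lat, gny = n_lat, gnz = n_z,
         voxel_mm = voxel_mm,
         cyl_on = !is.null(cyl_radius_cm),
         cxo = cyl_offset[1], cyo = cyl_offset[2],
         crad = cyl_radius_cm %||% 1, cz0 = 100, cdz = cyl_dz_mm / 10,
         cnz = as.integer(round(depth_cm / (cyl_dz_mm / 10))),
         prof_spec = matrix(numeric(0), ncol = 6),
         planes = planes %||% .empty_planes(),
         bin_w = 0.1, e_max = 10),
    class = "scoring_spec"
  )
}

#' @rdname scoring_grid
#' @param pdd_radius_cm Radius of the kerma depth-dose cylinder (cm).
#' @param pdd_dz_mm Depth bin of the kerma depth-dose cylinder (mm).
#' @param profile_depth_cm Depths (cm) of the lateral kerma profile slabs.
#' @param profile_halfthick_cm Half-thickness in z of each profile slab (cm).
#' @param profile_yhalf_cm Half-width in y over which the slab averages (cm).
#' @param profile_xhalf_cm Lateral half-extent of the profile (cm).
#' @param profile_dx_mm Lateral bin width (mm).
#' @param profile_axes Axes scored, `"x"`, `"y"` or both; with both, the
#'   beam's x/y symmetry gives two statistically independent copies of the
#'   same profile, which downstream consumers may average.
#' @export
scoring_kerma <- function(pdd_radius_cm = 2.5, pdd_dz_mm = 5,
                          cyl_offset = c(0, 0),
                          profile_depth_cm = 10, profile_halfthick_cm = 2,
                          profile_yhalf_cm = 2.5, profile_xhalf_cm = 15,
                          profile_dx_mm = 5, profile_axes = "x",
                          planes = NULL) {
  nxp <- as.integer(round(2 * profile_xhalf_cm / (profile_dx_mm / 10)))
  combos <- expand.grid(dep = profile_depth_cm, ax = profile_axes,
                        stringsAsFactors = FALSE)
  prof <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    dep <- combos$dep[i]
    c(100 + dep - profile_halfthick_cm, 100 + dep + profile_halfthick_cm,
      profile_yhalf_cm, -profile_xhalf_cm, profile_dx_mm / 10, nxp,
      if (combos$ax[i] == "x") 0 else 1)
  }))
  if (is.null(prof)) prof <- matrix(numeric(0), ncol = 7)
  structure(
    list(kerma_mode = TRUE,
         grid_on = FALSE, voxel_mm = NA_real_,
         cyl_on = TRUE, cxo = cyl_offset[1], cyo = cyl_offset[2],
         crad = pdd_radius_cm, cz0 = 100, cdz = pdd_dz_mm / 10,
         cnz = as.integer(round(40 / (pdd_dz_mm / 10))),
         prof_spec = prof, prof_depth_cm = combos$dep,
         prof_axis = combos$ax,
         planes = planes %||% .empty_planes(),
         bin_w = 0.1, e_max = 10),
    class = "scoring_spec"
  )
}

#' @rdname scoring_grid
#' @export
scoring_off <- function(planes = NULL) {
  structure(
    list(kerma_mode = FALSE, grid_on = FALSE, voxel_mm = NA_real_,
         cyl_on = FALSE, crad = 1, cxo = 0, cyo = 0, cz0 = 100, cdz = 0.5,
         cnz = 0,
         prof_spec = matrix(numeric(0), ncol = 6),
         planes = planes %||% .empty_planes(),
         bin_w = 0.1, e_max = 10),
    class = "scoring_spec"
  )
}

#' Spectral scoring plane at the phantom surface
#'
#' @param oad_cm Off-axis distance: the plane center is shifted by this
#'   amount along both x and y (the geometric distance from the CAX is
#'   `sqrt(2) * oad_cm`).
#' @param half_width_cm Half-side of the square plane (default 0.25 cm: the
#'   5x5 mm^2 convention).
#' @param z Plane z (cm); default the phantom surface.
#' @return One-row plane matrix; rows can be stacked with `rbind()`.
#' @export
surface_plane <- function(oad_cm = 0, half_width_cm = 0.25, z = 100) {
  matrix(c(z, oad_cm, oad_cm, half_width_cm), nrow = 1,
         dimnames = list(NULL, c("z", "xc", "yc", "hw")))
}

#' Full-field scoring plane
#'
#' A square plane covering the whole field at the given z.
#' @param field_cm Field side (cm); the plane half-width is `field_cm/2`.
#' @param z Plane z (cm).
#' @export
field_plane <- function(field_cm, z = 100) {
  matrix(c(z, 0, 0, field_cm / 2), nrow = 1,
         dimnames = list(NULL, c("z", "xc", "yc", "hw")))
}

# ---------------------------------------------------------------------------
# engine-model assembly

.mat_for_engine <- function(name, with_tr = FALSE) {
  m <- linac_material(name)
  tab <- m$attenuation_table
  out <- list(energy = tab$energy,
              pe = tab$photoelectric * m$density,
              co = tab$compton * m$density,
              pa = tab$pair * m$density,
              tot = tab$total * m$density)
  if (with_tr) out$tr <- .mu_tr_table(name)$mu_tr
  out
}

.engine_model <- function(head, source, run, scoring,
                          source_mode = 0L, pp_energy = 2, pp_cone = 0.01,
                          psf_records = NULL, psf_plane_z = 25,
                          absorb_only = FALSE) {
  bp <- .brems_params(source, head)
  filt <- head$filter_profile
  list(
    source = list(mean_energy = source$mean_energy,
                  sigma = source$energy_spread_sigma,
                  spot_sigma_cm = source$spot_fwhm_mm /
                    (2 * sqrt(2 * log(2))) / 10),
    head = list(flat = identical(head$mode, "flat"),
                t_target = head$target$thickness_mm / 10,
                z_pc = head$primary_collimator$z_exit,
                r_pc = tan(head$primary_collimator$half_angle) *
                  head$primary_collimator$z_exit,
                z_filter = head$filter_z,
                z_jaw = head$jaws$z_cm,
                ap_jaw = head$jaws$half_aperture_cm,
                z_psf = head$psf_plane_z,
                z_phantom = head$ssd,
                phantom_half = 20, phantom_depth = 40,
                filter_r = if (is.null(filt)) numeric(0) else
                  filt$radius_mm / 10,
                filter_t = if (is.null(filt)) numeric(0) else
                  filt$thickness_mm / 10),
    brems = bp,
    materials = list(water = .mat_for_engine("water", with_tr = TRUE),
                     air = .mat_for_engine("air"),
                     steel = .mat_for_engine("steel")),
    stopping_water = .stopping_power_table("water"),
    e_cut = range_cut_to_energy("water", run$cut_range_mm),
    photon_cut = 0.02,
    run = list(air_on = run$air_interactions,
               absorb_only = absorb_only,
               kill_electrons = run$kill_electrons_above_phantom,
               kerma_mode = scoring$kerma_mode,
               psf_capture = run$psf_capture,
               psf_max = 2000000L,
               source_mode = as.integer(source_mode),
               pp_energy = pp_energy, pp_cone = pp_cone,
               psf_records = psf_records %||% matrix(numeric(0), ncol = 8),
               psf_factor = as.integer(run$recycle_factor),
               psf_rotate = run$recycle_factor > 1,
               psf_plane_z = psf_plane_z),
    scoring = scoring[c("grid_on", "cyl_on", "prof_spec", "bin_w", "e_max")] |>
      c(list(gx0 = scoring$gx0 %||% 0, gy0 = scoring$gy0 %||% 0,
             gz0 = scoring$gz0 %||% 100, gd = scoring$gd %||% 0.5,
             gnx = scoring$gnx %||% 0L, gny = scoring$gny %||% 0L,
             gnz = scoring$gnz %||% 0L,
             cxo = scoring$cxo, cyo = scoring$cyo, crad = scoring$crad,
             cz0 = scoring$cz0, cdz = scoring$cdz, cnz = scoring$cnz,
             planes = {
               p <- scoring$planes
               if (is.data.frame(p)) p <- as.matrix(p)
               storage.mode(p) <- "double"
               p
             }))
  )
}

.batch_seeds <- function(seed, batches) {
  # documented counter scheme: child b = (seed * 1009 + 7919 * b) mod (2^31-1)
  as.integer((as.double(seed) * 1009 + 7919 * seq_len(batches)) %% 2147483646 + 1)
}

MEV_TO_J <- 1.602176634e-13

#' Run the Monte-Carlo simulation
#'
#' Generates primaries (or replays a phase space), transports them through
#' the treatment head, air and water phantom, and accumulates the requested
#' tallies in independent batches.
#'
#' @param head A [head_config()].
#' @param source A [source_config()] or a [new_phase_space()] object (the
#'   virtual-source workflow; see [recycle()] semantics in `run_config()`).
#' @param run A [run_config()].
#' @param scoring A scoring spec ([scoring_grid()], [scoring_kerma()],
#'   [scoring_off()]).
#' @return A `linac_run` object: dose grid and/or central-axis curve,
#'   spectral plane histograms, phase space (if captured), per-batch energy
#'   ledger, and a run report including the dose per primary electron at
#'   10 cm depth (the dose-rate surrogate).
#' @export
run_simulation <- function(head, source, run = run_config(),
                           scoring = scoring_grid()) {
  psf_mode <- inherits(source, "phase_space")
  if (psf_mode) {
    psf <- source
    source <- source_config(psf$header$source_mean_energy %||% 8.8,
                            psf$header$source_sigma %||% 0.4,
                            psf$header$source_spot_fwhm %||% 1)
    rec <- .psf_records_matrix(psf)
    model <- .engine_model(head, source, run, scoring, source_mode = 1L,
                           psf_records = rec, psf_plane_z = psf$header$plane_z)
    total_hist <- psf$header$n_original_histories * run$recycle_factor
  } else {
    model <- .engine_model(head, source, run, scoring)
    total_hist <- run$n_histories
  }
  nb <- run$batches
  seeds <- .batch_seeds(run$seed, nb)
  n_per <- ceiling(run$n_histories / nb)

  grid_acc <- NULL; cyl_acc <- NULL; prof_acc <- NULL
  ph_acc <- NULL; ps_acc <- NULL; pe_acc <- NULL
  ledger <- vector("list", nb)
  psf_rows <- list(); psf_total <- 0
  if (psf_mode) {
    idx <- split(seq_len(nrow(rec)), rep(seq_len(nb), length.out = nrow(rec)))
  }
  for (b in seq_len(nb)) {
    set.seed(seeds[b])
    if (psf_mode) {
      model$run$psf_records <- rec[idx[[b]], , drop = FALSE]
      res <- cpp_run_batch(model, length(idx[[b]]) * run$recycle_factor)
    } else {
      res <- cpp_run_batch(model, n_per)
    }
    if (scoring$grid_on) {
      if (is.null(grid_acc))
        grid_acc <- array(0, c(scoring$gnx, scoring$gny, scoring$gnz, nb))
      grid_acc[, , , b] <- array(res$grid,
                                 c(scoring$gnx, scoring$gny, scoring$gnz))
    }
    if (scoring$cyl_on) {
      if (is.null(cyl_acc)) cyl_acc <- matrix(0, scoring$cnz, nb)
      cyl_acc[, b] <- res$cyl
    }
    if (nrow(scoring$prof_spec) > 0) {
      if (is.null(prof_acc))
        prof_acc <- lapply(res$prof, function(p) matrix(0, length(p), nb))
      for (k in seq_along(res$prof)) prof_acc[[k]][, b] <- res$prof[[k]]
    }
    npl <- nrow(scoring$planes)
    if (npl > 0) {
      nbin <- round(scoring$e_max / scoring$bin_w)
      if (is.null(ph_acc)) {
        ph_acc <- array(0, c(nbin, 2, npl, nb))
        ps_acc <- array(0, c(2, npl, nb)); pe_acc <- array(0, c(2, npl, nb))
      }
      ph_acc[, , , b] <- aperm(array(res$plane_hist, c(nbin, 2, npl)),
                               c(1, 2, 3))
      ps_acc[, , b] <- array(res$plane_sum, c(2, npl))
      pe_acc[, , b] <- array(res$plane_esum, c(2, npl))
    }
    ledger[[b]] <- res$ledger
    if (run$psf_capture && !is.null(res$psf) && nrow(res$psf) > 0) {
      psf_rows[[length(psf_rows) + 1]] <- res$psf
      psf_total <- psf_total + res$psf_total
    }
  }
  n_run <- if (psf_mode) total_hist else n_per * nb
  led <- dplyr::bind_rows(lapply(ledger, function(l) tibble::as_tibble(as.list(l))))

  out <- list(head = head, source = source, run = run, scoring = scoring,
              n_histories = n_run, ledger = led)
  if (scoring$grid_on) {
    out$dose <- new_dose_grid(grid_acc, scoring$voxel_mm,
                              origin_cm = c(scoring$gx0, scoring$gy0,
                                            scoring$gz0),
                              n_histories = n_run)
  }
  if (scoring$cyl_on) {
    mass_kg <- pi * scoring$crad^2 * scoring$cdz / 1000  # water, kg
    depth_mm <- (seq_len(scoring$cnz) - 0.5) * scoring$cdz * 10
    dose_gy <- rowSums(cyl_acc) / n_run * MEV_TO_J / mass_kg
    unc <- .batch_rel_se(cyl_acc)
    out$cax_pdd <- scan_curve(depth_mm, dose_gy, kind = "pdd",
                              unc_pct = unc,
                              meta = list(tally = "cylinder",
                                          radius_cm = scoring$crad,
                                          offset = c(scoring$cxo, scoring$cyo)))
    out$cyl_batches <- cyl_acc
  }
  if (!is.null(prof_acc)) {
    out$profiles <- lapply(seq_along(prof_acc), function(k) {
      sp <- scoring$prof_spec[k, ]
      vol_kg <- sp[5] * (2 * sp[3]) * (sp[2] - sp[1]) / 1000
      pos <- (sp[4] + (seq_len(sp[6]) - 0.5) * sp[5]) * 10
      scan_curve(pos, rowSums(prof_acc[[k]]) / n_run * MEV_TO_J / vol_kg,
                 kind = "profile", unc_pct = .batch_rel_se(prof_acc[[k]]),
                 meta = list(depth_cm = scoring$prof_depth_cm[k],
                             axis = scoring$prof_axis[k] %||% "x",
                             tally = "kerma_slab"))
    })
  }
  if (!is.null(ph_acc)) {
    out$spectra <- .planes_to_spectra(ph_acc, ps_acc, pe_acc,
                                      scoring, n_run)
  }
  if (run$psf_capture) {
    recs <- if (length(psf_rows)) do.call(rbind, psf_rows) else
      matrix(numeric(0), ncol = 8)
    out$psf <- new_phase_space(recs, plane_z = head$psf_plane_z,
                               n_original_histories = n_run,
                               source = source)
  }
  # report: dose per primary at 10 cm depth on the (possibly offset) axis
  report <- list(n_histories = n_run)
  if (!is.null(out$cax_pdd)) {
    report$dose_per_primary_10cm <-
      stats::approx(out$cax_pdd$position_mm, out$cax_pdd$dose, xout = 100)$y
  } else if (scoring$grid_on) {
    pdd <- extract_pdd(out$dose)
    report$dose_per_primary_10cm <-
      stats::approx(pdd$position_mm, pdd$dose, xout = 100)$y
  }
  if (nrow(led) && !scoring$kerma_mode) {
    report$energy_balance <- with(as.list(colSums(led)),
      (deposited + exited) / (enter + 1e-300))
  }
  out$report <- report
  class(out) <- "linac_run"
  out
}

#' @export
print.linac_run <- function(x, ...) {
  cat("<linac_run> ", x$head$mode, " ", x$head$field_cm, "x",
      x$head$field_cm, " cm, ", format(x$n_histories, big.mark = ","),
      " histories\n", sep = "")
  if (!is.null(x$report$dose_per_primary_10cm)) {
    cat("  dose/primary at 10 cm depth: ",
        signif(x$report$dose_per_primary_10cm, 4), " Gy\n", sep = "")
  }
  invisible(x)
}

.batch_rel_se <- function(m) {
  nb <- ncol(m)
  mu <- rowMeans(m)
  se <- apply(m, 1, stats::sd) / sqrt(nb)
  ifelse(mu > 0, 100 * se / mu, 0)
}

.planes_to_spectra <- function(ph_acc, ps_acc, pe_acc, scoring, n_run) {
  npl <- dim(ph_acc)[3]
  nbin <- dim(ph_acc)[1]
  edges <- seq(0, scoring$e_max, by = scoring$bin_w)
  kinds <- c("photon", "electron")
  res <- list()
  for (i in seq_len(npl)) {
    for (k in 1:2) {
      h <- apply(ph_acc[, k, i, , drop = FALSE], 1, sum) / n_run
      res[[paste0("plane", i, "_", kinds[k])]] <-
        spectrum_histogram(edges[-length(edges)], edges[-1], h,
                           kind = kinds[k],
                           plane = as.list(as.data.frame(
                             scoring$planes))[c("z", "xc", "yc", "hw")] |>
                             lapply(function(v) v[i]))
    }
  }
  res
}
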