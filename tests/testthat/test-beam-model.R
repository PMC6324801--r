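# Electron source, head geometry, presets and the flattening-filter design.

test_that("primary electron sampling follows the source model", {
  src <- source_config(8.8, 0, 1)
  set.seed(1)
  e <- sample_primary_electron(1000, src)
  expect_true(all(e$energy == 8.8))            # zero spread is degenerate
  expect_true(all(e$u == 0 & e$v == 0 & e$w == 1))

  set.seed(2)
  e2 <- sample_primary_electron(5e5, fff7mv_source())
  sigma_exp <- 1 / (2 * sqrt(2 * log(2)))      # 0.4247 mm for 1 mm FWHM
  se <- sigma_exp / sqrt(2 * nrow(e2))
  expect_lt(abs(stats::sd(e2$x_mm) - sigma_exp), 3 * se)
  expect_true(all(e2$energy > 0))
})

test_that("beam-line presets carry the commissioned source parameters", {
  s <- fff7mv_source()
  expect_equal(c(s$mean_energy, s$energy_spread_sigma, s$spot_fwhm_mm),
               c(8.8, 0.4, 1))
  expect_equal(flat6mv_source()$mean_energy, 7.5)
  cfg <- read_beam_config("fff7mv")
  expect_equal(cfg$source$mean_energy, 8.8)
  expect_identical(cfg$head$mode, "fff")
})

test_that("head configuration enforces its invariants", {
  expect_error(head_config("fff", filter_profile = data.frame()), "filter")
  h <- head_config("fff", field_cm = 10)
  expect_equal(h$jaws$half_aperture_cm, 10 / 2 * 30 / 100)
})

test_that("collimation absorbs out-of-aperture photons and FFF passes unchanged", {
  h <- fff7mv_head(10)
  onax <- tibble::tibble(kind = "photon", energy = 2, x_mm = 0, y_mm = 0,
                         z_mm = 5, u = 0, v = 0, w = 1, weight = 1)
  out <- transmit_through_head(onax, h, air = FALSE)
  expect_equal(nrow(out), 1)
  expect_equal(out$energy, 2)                  # FFF pass-through
  wide <- onax
  wide$u <- 0.25; wide$w <- sqrt(1 - 0.25^2)   # beyond the jaw aperture
  expect_equal(nrow(transmit_through_head(wide, h, air = FALSE)), 0)
})

test_that("the flattening filter hardens the transmitted spectrum", {
  hl <- flat6mv_head(10)
  set.seed(21)
  stream <- tibble::tibble(kind = "photon",
                           energy = runif(4000, 0.3, 3),
                           x_mm = 0, y_mm = 0, z_mm = 5,
                           u = 0, v = 0, w = 1, weight = 1)
  out <- transmit_through_head(stream, hl, air = FALSE)
  surv <- out[out$kind == "photon" & abs(out$x_mm) < 30, ]
  expect_lt(nrow(surv), nrow(stream))          # filter removes photons
  expect_gt(mean(surv$energy), mean(stream$energy))
})

test_that("filter design returns a monotone profile and a null filter for flat fluence", {
  f <- design_flattening_filter()
  expect_true(all(diff(f$thickness_mm) <= 1e-9))
  expect_gt(f$thickness_mm[1], 0)
  expect_lt(max(abs(attr(f, "residual"))), 0.02)
  # an already-uniform fluence needs no correction
  f0 <- design_flattening_filter(
    fluence_profile = function(theta) rep(1, length(theta)))
  # only the cos^3 obliquity survives; the implied correction is sub-mm
  expect_lt(max(f0$thickness_mm), 1.5)
})

test_that("the designed filter flattens the beam and removing it restores the cone", {
  hl40 <- flat6mv_head(40)
  s <- run_simulation(hl40, flat6mv_source(),
                      run_config(4e7, seed = 66, batches = 2),
                      scoring_kerma(profile_xhalf_cm = 20))
  pn <- normalize_curve(s$profiles[[1]], "cax")
  # smooth the 5 mm bins before judging flatness so single-bin Monte-Carlo
  # excursions do not masquerade as beam structure
  sm <- signal::sgolayfilt(pn$dose, p = 2, n = 9)
  infield <- sm[abs(pn$position_mm) <= 160]
  expect_lt(max(infield) / min(infield), 1.15)
  # FFF mode: forward-peaked cone, unflatness > 1 for all fields
  for (field in c(10, 40)) {
    sf <- kerma_run("fff", field, n = if (field == 10) 2e7 else 2e7,
                    seed = 603 + field, xhalf = 20)
    pf <- normalize_curve(sf$profiles[[1]], "cax")
    fs_mm <- field * 10 * 1.1                 # geometric size at 10 cm depth
    expect_gt(unflatness(pf, field_size_mm = fs_mm), 1.02)
  }
})
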