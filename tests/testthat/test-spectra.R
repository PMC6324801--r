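# Fluence histograms, mean energies, staged head fluence and off-axis scans.

test_that("binning assigns energies to 0.1 MeV intervals and conserves weight", {
  st <- tibble::tibble(energy = rep(2.05, 10), weight = rep(0.5, 10))
  h <- bin_fluence(st)
  i <- which(h$bin_low == 2.0)
  expect_equal(h$fluence[i], 5)
  expect_equal(sum(h$fluence), sum(st$weight))
  # five-particle hand fixture
  st5 <- tibble::tibble(energy = c(0.05, 0.14, 0.16, 5.25, 11),
                        weight = c(1, 2, 3, 4, 5))
  h5 <- bin_fluence(st5)
  expect_equal(h5$fluence[h5$bin_low == 0.0], 1)
  expect_equal(h5$fluence[h5$bin_low == 0.1], 5)     # 0.14 and 0.16 share a bin
  expect_equal(h5$fluence[h5$bin_low == 5.2], 4)
  expect_equal(h5$fluence[h5$bin_low == 9.9], 5)     # clamped into last bin
  expect_equal(sum(h5$fluence), 15)
})

test_that("mean energy averages bin centers by fluence", {
  h <- spectrum_histogram(c(1.0), c(1.1), c(3))
  expect_equal(mean_energy(h), 1.05)
  h2 <- spectrum_histogram(c(1.0, 2.0), c(1.1, 2.1), c(2, 2))
  expect_equal(mean_energy(h2), (1.05 + 2.05) / 2)
  empty <- spectrum_histogram(c(1.0), c(1.1), c(0))
  expect_error(mean_energy(empty), "empty")
  expect_error(spectrum_histogram(c(1), c(1.1), c(-1)), "non-negative")
})

test_that("the phase-space spectrum equals the live plane spectrum bin by bin", {
  h <- fff7mv_head(10)
  planes <- matrix(c(25, 0, 0, 20), nrow = 1,
                   dimnames = list(NULL, c("z", "xc", "yc", "hw")))
  s <- run_simulation(h, fff7mv_source(),
                      run_config(2e5, seed = 55, batches = 1,
                                 psf_capture = TRUE),
                      scoring_off(planes = planes))
  live <- s$spectra$plane1_photon
  st <- recycle(s$psf, 1)
  # the live tally is windowed to the plane; window the records identically
  psf_hist <- bin_fluence(st[st$kind == "photon", ],
                          plane = list(xc = 0, yc = 0, hw = 20))
  expect_equal(psf_hist$fluence, live$fluence * s$n_histories,
               tolerance = 1e-9)
})

test_that("head fluence hardens and thins downstream of the target", {
  sf <- staged_fluence(fff7mv_head(10), fff7mv_source(),
                       run_config(2e6, seed = 78, batches = 2))
  s <- sf$summary
  ph <- s[s$kind == "photon", ]
  expect_true(all(diff(ph$fluence_per_primary) < 0))     # absorption only
  # with a separable (angle-independent) emission spectrum only the air
  # column hardens the beam, so the downstream mean energy is equal or
  # slightly higher, never softer beyond the Monte-Carlo noise
  expect_gt(ph$mean_energy[3], ph$mean_energy[1] - 0.02)
  el <- s[s$kind == "electron", ]
  # contaminant electrons build up in the air column and slow down
  expect_gt(el$fluence_per_primary[3], 0)
  expect_lt(el$mean_energy[3], el$mean_energy[2])
})

test_that("FFF off-axis spectra are radius-independent, flattened ones soften", {
  run <- run_config(2e6, seed = 91)
  fff <- offaxis_spectrum_scan(fff7mv_head(20), fff7mv_source(), run)
  expect_lt(max(abs(fff$mean_energy$rel_dev_pct)), 0.5)
  expect_true(all(diff(fff$mean_energy$fluence_per_primary) < 0))
  flat <- offaxis_spectrum_scan(flat6mv_head(20), flat6mv_source(), run)
  me <- flat$mean_energy$mean_energy
  expect_true(all(diff(me) < 0))                         # softening with OAD
  expect_gt((me[1] - me[4]) / me[1], 0.03)               # a real effect
  # a plane outside the field warns
  expect_warning(
    offaxis_spectrum_scan(fff7mv_head(10), fff7mv_source(),
                          run_config(1e4, seed = 1), oads = c(9)),
    "field")
})

test_that("next-event and analog off-axis estimators agree", {
  run_ne <- run_config(2e6, seed = 92)
  ne <- offaxis_spectrum_scan(fff7mv_head(20), fff7mv_source(), run_ne,
                              oads = c(5), estimator = "nextevent")
  an <- offaxis_spectrum_scan(fff7mv_head(20), fff7mv_source(),
                              run_config(4e7, seed = 93, batches = 2),
                              oads = c(5), estimator = "analog")
  for (i in 1:2) {
    me_ne <- ne$mean_energy$mean_energy[i]
    me_an <- an$mean_energy$mean_energy[i]
    n_an <- an$mean_energy$fluence_per_primary[i] * 4e7
    tol <- 3 * 0.75 * me_an / sqrt(n_an) + 0.02 * me_an
    expect_lt(abs(me_ne - me_an), tol)
  }
  expect_equal(ne$mean_energy$fluence_per_primary[2],
               an$mean_energy$fluence_per_primary[2], tolerance = 0.15)
})

test_that("inserting the flattening filter raises the CAX mean energy", {
  run <- run_config(1e6, seed = 94)
  fff <- offaxis_spectrum_scan(fff7mv_head(10), flat6mv_source(), run,
                               oads = numeric(0))
  flat <- offaxis_spectrum_scan(flat6mv_head(10), flat6mv_source(), run,
                                oads = numeric(0))
  expect_gt(flat$mean_energy$mean_energy[1], fff$mean_energy$mean_energy[1])
})
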