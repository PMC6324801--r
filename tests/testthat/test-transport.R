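# Monte-Carlo engine contracts: reproducibility, conservation, cut-off
# semantics, buildup physics and the electron-kill contrast.

test_that("identical seeds give bitwise-identical dose grids", {
  h <- fff7mv_head(10); src <- fff7mv_source()
  a <- run_simulation(h, src, run_config(5e4, seed = 42, batches = 2),
                      scoring_grid(voxel_mm = 5))
  b <- run_simulation(h, src, run_config(5e4, seed = 42, batches = 2),
                      scoring_grid(voxel_mm = 5))
  expect_identical(a$dose$batch_edep, b$dose$batch_edep)
  expect_identical(a$cyl_batches, b$cyl_batches)
})

test_that("phantom energy bookkeeping closes", {
  h <- fff7mv_head(10)
  s <- run_simulation(h, fff7mv_source(),
                      run_config(2e5, seed = 3, batches = 2),
                      scoring_grid(voxel_mm = 5))
  expect_lt(abs(s$report$energy_balance - 1), 1e-3)
})

test_that("electron cut-off semantics deposit locally below threshold", {
  m <- linacmc:::.engine_model(fff7mv_head(10), fff7mv_source(),
                               run_config(),
                               scoring_grid(voxel_mm = 1,
                                            half_extent_cm = 2,
                                            depth_cm = 6))
  e_cut <- range_cut_to_energy("water", 1)
  set.seed(5)
  below <- linacmc:::cpp_electron_track(e_cut * 0.9, c(0, 0, 101),
                                        c(0, 0, 1), m)
  g <- array(below$grid, c(40, 40, 60))
  expect_equal(below$deposited, e_cut * 0.9)
  expect_equal(sum(g > 0), 1)                 # a single voxel, zero steps
  # full track conserves kinetic energy (no radiative losses in water)
  set.seed(6)
  tr <- linacmc:::cpp_electron_track(2.0, c(0, 0, 101), c(0, 0, 1), m)
  expect_equal(tr$deposited + tr$exited, 2.0, tolerance = 1e-9)
})

test_that("the buildup region has the megavoltage shape with its plateau at dmax", {
  # the argmax of a noisy, nearly flat plateau is not a stable statistic at
  # desk scale, so the buildup physics is asserted through the curve shape:
  # low surface dose, steep rise, near-maximum dose at the machine's dmax
  # (19 mm FFF / 16 mm flattened), deeper rise for the harder FFF beam
  level <- function(p, z) {
    sm <- signal::sgolayfilt(p$dose, p = 2, n = 11)
    100 * stats::approx(p$position_mm, sm, xout = z)$y / max(sm)
  }
  d80 <- function(p) {
    sm <- signal::sgolayfilt(p$dose, p = 2, n = 11)
    p$position_mm[which(sm >= 0.8 * max(sm))[1]]
  }
  fff <- attr(cc_run("fff", 10), "runs")$full$cax_pdd
  flat <- attr(cc_run("flat", 10), "runs")$full$cax_pdd
  expect_lt(level(fff, 0.5), 60)
  expect_lt(level(flat, 0.5), 60)
  expect_gt(level(fff, 19), 80)          # near-max at the published dmax
  expect_gt(level(flat, 16), 80)
  expect_lt(level(fff, 5), level(fff, 18))   # rising buildup
  expect_lt(level(flat, 4), level(flat, 15))
  expect_gt(d80(fff), d80(flat) - 3)     # harder beam builds up deeper
})

test_that("electron-kill removes the contaminant surface dose component", {
  cr <- cc_run("flat", 10)
  expect_lt(cr$surface_killed_pct, cr$surface_full_pct)
  runs <- attr(cr, "runs")
  # the paired difference of the curves is the contamination depth profile
  diff0 <- runs$full$cax_pdd$dose[1] - runs$killed$cax_pdd$dose[1]
  expect_gt(diff0, 0)
  expect_gt(sum(runs$killed$ledger$killed), 0)
})

test_that("statistical error scales as one over the square root of histories", {
  h <- fff7mv_head(10); src <- fff7mv_source()
  sc <- scoring_kerma()
  reps <- 24
  est <- function(n, base_seed) {
    sapply(seq_len(reps), function(r) {
      s <- run_simulation(h, src, run_config(n, seed = base_seed + r,
                                             batches = 1), sc)
      s$cax_pdd$dose[2:70]
    })
  }
  m1 <- est(4e5, 7000)
  m2 <- est(1.6e6, 8000)
  sd1 <- apply(m1, 1, stats::sd) / rowMeans(m1)
  sd2 <- apply(m2, 1, stats::sd) / rowMeans(m2)
  expo <- mean(log(sd2 / sd1)) / log(4)
  expect_lt(abs(expo + 0.5), 0.1)
})

test_that("weights are conserved through the analog chain into the phase space", {
  h <- fff7mv_head(10)
  s <- run_simulation(h, fff7mv_source(),
                      run_config(5e4, seed = 9, batches = 1,
                                 psf_capture = TRUE), scoring_off())
  rec <- s$psf$records
  # analog transport never alters a weight after emission: every record's
  # weight is the emission weight n(E0) * Tbar(k), hence positive and bounded
  expect_true(all(rec[, "weight"] > 0))
  expect_true(all(rec[, "weight"] < 5))
})
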