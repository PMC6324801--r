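# Dose-grid extraction, normalization, surface dose and uncertainty.

test_that("depth-dose extraction picks the requested column", {
  # grid whose voxel values encode their own (ix, iy) indices
  nx <- 21
  a <- array(0, c(nx, nx, 10, 1))
  for (i in seq_len(nx)) for (j in seq_len(nx)) a[i, j, , 1] <- i * 1000 + j
  g <- new_dose_grid(a, voxel_mm = 10, origin_cm = c(-10.5, -10.5, 100))
  # central axis
  p0 <- extract_pdd(g)
  expect_equal(stats::sd(p0$dose), 0)          # constant along depth
  # an offset of 7.5 cm is applied to both x and y (radius 7.5*sqrt(2))
  p <- extract_pdd(g, lateral_offset_cm = 7.5)
  centers <- (-10.5 + (seq_len(nx) - 0.5))     # cm
  d7 <- abs(centers - 7.5)
  ix <- max(which(d7 == min(d7)))              # ties break toward +x

  mass <- 1e-3
  val <- (ix * 1000 + ix) / g$n_histories * 1.602176634e-13 / mass
  expect_equal(p$dose[1], val)
  expect_error(extract_pdd(g, 30), "outside")
})

test_that("normalization contracts hold", {
  z <- seq(0.5, 300, 1)
  d <- (1 - exp(-0.2 * z)) * exp(-0.004 * z)
  pdd <- scan_curve(z, d, kind = "pdd")
  n <- normalize_curve(pdd)
  expect_equal(max(n$dose), 100)
  expect_identical(attr(n, "normalization"), "dmax")
  # uniform grid gives a constant extracted curve
  g <- new_dose_grid(array(2, c(5, 5, 8, 1)), voxel_mm = 10,
                     origin_cm = c(-2.5, -2.5, 100))
  expect_equal(stats::sd(extract_pdd(g)$dose), 0)
})

test_that("profiles come from the layer at the requested depth", {
  a <- array(0, c(11, 11, 4, 1))
  a[, , 3, 1] <- outer(abs(seq(-5, 5)), rep(1, 11), function(i, j) 10 - i)
  g <- new_dose_grid(a, voxel_mm = 10, origin_cm = c(-5.5, -5.5, 100))
  p <- extract_profile(g, depth_cm = 2.5, axis = "x")
  expect_equal(length(p$position_mm), 11)
  expect_equal(p$dose, rev(p$dose))            # symmetric fixture
  expect_error(extract_profile(g, depth_cm = 50), "outside")
})

test_that("surface dose follows the 1 mm contract", {
  a <- array(1, c(5, 5, 30, 1))
  g1 <- new_dose_grid(a, voxel_mm = 1, origin_cm = c(-0.25, -0.25, 100))
  expect_equal(surface_dose(g1), 100)          # constant grid
  g5 <- new_dose_grid(a, voxel_mm = 5, origin_cm = c(-1.25, -1.25, 100))
  expect_error(surface_dose(g5), "1 mm")
  # buildup-shaped column: surface well below the maximum
  b <- array(rep(1 - exp(-0.3 * (1:30)), each = 25), c(5, 5, 30, 1))
  g2 <- new_dose_grid(b, voxel_mm = 1, origin_cm = c(-0.25, -0.25, 100))
  expect_lt(surface_dose(g2), 40)
})

test_that("batch uncertainty matches the direct formula", {
  b <- array(0, c(1, 1, 1, 3))
  b[1, 1, 1, ] <- c(9, 10, 11)
  g <- new_dose_grid(b, voxel_mm = 5, n_histories = 10)
  u <- estimate_uncertainty(g)
  expect_equal(u[1, 1, 1], 100 * stats::sd(c(9, 10, 11)) / sqrt(3) / 10)
  # identical batches have zero estimated error
  same <- new_dose_grid(array(4, c(2, 2, 2, 4)), voxel_mm = 5)
  expect_true(all(estimate_uncertainty(same) == 0))
  expect_error(estimate_uncertainty(
    new_dose_grid(array(1, c(2, 2, 2, 1)), voxel_mm = 5)), "batches")
})

test_that("the cylindrical tally agrees with the voxel central-axis column", {
  h <- fff7mv_head(10)
  s <- run_simulation(h, fff7mv_source(),
                      run_config(8e6, seed = 88, batches = 4),
                      scoring_grid(voxel_mm = 5, cyl_radius_cm = 1))
  pdd_vox <- extract_pdd(s$dose)
  pdd_cyl <- s$cax_pdd
  for (depth in c(50, 100, 200)) {
    v <- stats::approx(pdd_vox$position_mm, pdd_vox$dose, xout = depth)$y
    cy <- stats::approx(pdd_cyl$position_mm, pdd_cyl$dose, xout = depth)$y
    uv <- stats::approx(pdd_vox$position_mm, pdd_vox$unc_pct, xout = depth)$y
    uc <- stats::approx(pdd_cyl$position_mm, pdd_cyl$unc_pct, xout = depth)$y
    tol <- 3 * sqrt(uv^2 + uc^2) / 100 * max(v, cy) + 1e-18
    expect_lt(abs(v - cy), tol)
  }
})

test_that("dose grids and scan curves survive serialization", {
  g <- new_dose_grid(array(runif(8), c(2, 2, 2, 1)), voxel_mm = 5,
                     n_histories = 7)
  f <- withr::local_tempfile(fileext = ".rds")
  write_dose_grid(g, f)
  g2 <- read_dose_grid(f)
  expect_equal(g2$batch_edep, g$batch_edep)
  expect_equal(dose_array(g2), dose_array(g))
  cv <- scan_curve(1:10, (1:10)^2, kind = "profile", normalization = "cax")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_scan_curve(cv, fc)
  cv2 <- read_scan_curve(fc)
  expect_equal(cv2$position_mm, cv$position_mm)
  expect_equal(cv2$dose, cv$dose)
  expect_identical(attr(cv2, "kind"), "profile")
  expect_identical(attr(cv2, "normalization"), "cax")
})
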