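# Phase-space format, integrity checks and recycling semantics.

make_psf <- function(n = 5, n_orig = 1000, plane_z = 25) {
  rec <- cbind(kind = rep(0, n), energy = seq(0.5, by = 0.5, length.out = n),
               x_mm = seq(-10, 10, length.out = n), y_mm = rep(2, n),
               u = rep(0.05, n), v = rep(0, n),
               w = rep(sqrt(1 - 0.05^2), n), weight = rep(1.2, n))
  new_phase_space(rec, plane_z = plane_z, n_original_histories = n_orig,
                  source = fff7mv_source())
}

test_that("write/read round trip reproduces all record fields exactly", {
  psf <- make_psf(7)
  f <- withr::local_tempfile(fileext = ".bpsf")
  write_psf(psf, f)
  p2 <- read_psf(f)
  expect_identical(unname(p2$records), unname(psf$records))
  expect_equal(p2$header$plane_z, 25)
  expect_equal(p2$header$n_original_histories, 1000)
  expect_equal(p2$header$source_mean_energy, 8.8)
})

test_that("a hand-built binary file parses to the hand-built records", {
  # bytes written directly following the documented layout
  f <- withr::local_tempfile(fileext = ".bpsf")
  con <- file(f, "wb")
  writeBin(charToRaw("BPSF"), con)
  writeBin(1L, con, size = 4, endian = "little")
  hd <- c(25, 500, 3, 8.8, 0.4, 1.0)
  writeBin(hd, con, size = 8, endian = "little")
  writeBin(sum(hd), con, size = 8, endian = "little")
  recs <- rbind(c(0, 1.5, 1, 2, 0, 0, 1, 1),
                c(1, 0.8, -3, 0, 0.1, 0, sqrt(1 - 0.01), 1),
                c(0, 6.2, 0, 0, 0, 0, 1, 0.5))
  writeBin(as.vector(t(recs)), con, size = 8, endian = "little")
  writeBin(sum(recs[, 2]), con, size = 8, endian = "little")
  close(con)
  p <- read_psf(f)
  expect_equal(p$header$n_records, 3)
  expect_equal(unname(p$records), unname(recs))
})

test_that("corrupt or truncated files fail with the byte offset named", {
  psf <- make_psf(4)
  f <- withr::local_tempfile(fileext = ".bpsf")
  write_psf(psf, f)
  raw <- readBin(f, "raw", file.size(f))
  # truncate one record
  writeBin(raw[1:(length(raw) - 64)], f)
  expect_error(read_psf(f), "byte offset")
  # corrupt the header count
  raw2 <- raw
  raw2[33:40] <- writeBin(99, raw(), size = 8, endian = "little")
  writeBin(raw2, f)
  expect_error(read_psf(f), "checksum|byte offset")
  # bad magic
  raw3 <- raw
  raw3[1] <- as.raw(0)
  writeBin(raw3, f)
  expect_error(read_psf(f), "offset 0")
})

test_that("recycling multiplies records with azimuthal re-randomisation", {
  psf <- make_psf(5, n_orig = 1.5e9)
  out5 <- recycle(psf, 5, seed = 3)
  expect_equal(nrow(out5), 25)
  expect_equal(attr(out5, "equivalent_histories"), 7.5e9)
  # energies and radii are preserved by the rotation
  expect_equal(sort(unique(out5$energy)), sort(unique(psf$records[, "energy"])))
  r_in <- sqrt(psf$records[, "x_mm"]^2 + psf$records[, "y_mm"]^2)
  r_out <- sqrt(out5$x_mm^2 + out5$y_mm^2)
  expect_equal(sort(rep(r_in, 5)), sort(r_out), tolerance = 1e-12)
  # factor 1 is the identity (no rotation)
  out1 <- recycle(psf, 1)
  expect_equal(out1$x_mm, psf$records[, "x_mm"])
  expect_equal(attr(out1, "equivalent_histories"), 1.5e9)
  # rotation is only valid above the jaws
  low <- make_psf(3, plane_z = 50)
  expect_error(recycle(low, 5), "jaws")
})

test_that("fluence spectra are invariant under recycling", {
  h <- fff7mv_head(10)
  s <- run_simulation(h, fff7mv_source(),
                      run_config(3e5, seed = 77, batches = 1,
                                 psf_capture = TRUE), scoring_off())
  psf <- s$psf
  base <- recycle(psf, 1)
  rec <- recycle(psf, 4, seed = 5)
  h1 <- bin_fluence(base[base$kind == "photon", ])
  h4 <- bin_fluence(rec[rec$kind == "photon", ])
  expect_equal(h4$fluence / sum(h4$fluence), h1$fluence / sum(h1$fluence),
               tolerance = 1e-12)   # rotation cannot change the spectrum
})

test_that("recycling reduces variance, but less than fresh histories would", {
  h <- fff7mv_head(10); src <- fff7mv_source()
  pv <- function(sim) {
    p <- sim$profiles[[1]]
    stats::approx(p$position_mm, p$dose, xout = 30)$y
  }
  reps <- 32
  v1 <- v5 <- vf <- numeric(reps)
  for (r in seq_len(reps)) {
    s <- run_simulation(h, src, run_config(3e4, seed = 1000 + r, batches = 1,
                                           psf_capture = TRUE), scoring_off())
    psf <- s$psf
    v1[r] <- pv(run_simulation(h, psf, run_config(seed = 2000 + r, batches = 1,
                                                  recycle_factor = 1),
                               scoring_kerma()))
    v5[r] <- pv(run_simulation(h, psf, run_config(seed = 3000 + r, batches = 1,
                                                  recycle_factor = 5),
                               scoring_kerma()))
    vf[r] <- pv(run_simulation(h, src, run_config(1.5e5, seed = 4000 + r,
                                                  batches = 1),
                               scoring_kerma()))
  }
  rsd <- function(v) stats::sd(v) / mean(v)
  expect_lt(rsd(v5), rsd(v1))
  # recycled particles stay correlated, so five reuses cannot beat five
  # times the fresh histories (0.75 allows for the replicate-count noise of
  # the standard-deviation estimates themselves)
  expect_gt(rsd(v5), rsd(vf) * 0.75)
})

test_that("a phase space drives the simulation as a virtual source", {
  h <- fff7mv_head(10)
  s <- run_simulation(h, fff7mv_source(),
                      run_config(2e5, seed = 31, batches = 2,
                                 psf_capture = TRUE), scoring_off())
  sim <- run_simulation(h, s$psf,
                        run_config(seed = 32, batches = 2,
                                   recycle_factor = 2), scoring_kerma())
  expect_equal(sim$n_histories, s$psf$header$n_original_histories * 2)
  expect_gt(sim$report$dose_per_primary_10cm, 0)
  d <- d20_d10(sim$cax_pdd)
  expect_gt(d, 0.4); expect_lt(d, 0.8)
})
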