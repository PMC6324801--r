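# Embedded interaction data and sampling primitives.

test_that("attenuation coefficients interpolate the embedded tables", {
  w <- linac_material("water")
  tab <- w$attenuation_table
  # exact at a table node
  i <- which(tab$energy == 2)
  expect_equal(attenuation_coefficient(w, 2, "total"),
               tab$total[i] * w$density)
  # off-node value agrees with an independent log-log interpolation
  e <- 2.5
  j <- findInterval(e, tab$energy)
  f <- (log(e) - log(tab$energy[j])) /
    (log(tab$energy[j + 1]) - log(tab$energy[j]))
  oracle <- exp(log(tab$total[j]) + f * (log(tab$total[j + 1]) -
                                           log(tab$total[j]))) * w$density
  expect_equal(attenuation_coefficient(w, e), oracle, tolerance = 0.005)
  # channels sum to the total at every node
  expect_equal(tab$photoelectric + tab$compton + tab$pair, tab$total,
               tolerance = 1e-9)
  # energy nodes strictly increasing, all coefficients positive
  expect_true(all(diff(tab$energy) > 0))
  expect_true(all(tab$photoelectric > 0 & tab$compton > 0 & tab$pair > 0))
})

test_that("water attenuation decreases monotonically from 0.1 to 4 MeV", {
  e <- seq(0.1, 4, length.out = 80)
  mu <- attenuation_coefficient("water", e)
  expect_true(all(diff(mu) < 0))
})

test_that("energies outside the tabulated range are rejected", {
  expect_error(attenuation_coefficient("water", 0.005), "range")
  expect_error(attenuation_coefficient("water", 25), "range")
})

test_that("range cut inverts the CSDA table", {
  w <- linac_material("water")
  # independent linear scan of the embedded table
  cut_gcm2 <- 0.1 * w$density   # 1 mm in water
  oracle <- w$csda_table$energy[which(w$csda_table$range >= cut_gcm2)[1]]
  expect_equal(range_cut_to_energy("water", 1), oracle)
  # degenerate and monotone cases
  expect_equal(range_cut_to_energy("water", 0), min(w$csda_table$energy))
  expect_gte(range_cut_to_energy("water", 2), range_cut_to_energy("water", 1))
  expect_error(range_cut_to_energy("water", 1e5), "beyond")
})

test_that("Compton sampler conserves energy and matches Klein-Nishina moments", {
  set.seed(11)
  s <- linacmc:::cpp_sample_compton(1e6, 1.0)
  expect_equal(s[, 1] + s[, 2], rep(1.0, nrow(s)), tolerance = 1e-12)
  # quadrature oracle for the mean scattered energy at 1 MeV
  a <- 1 / 0.511
  eps <- seq(1 / (1 + 2 * a), 1, length.out = 40001)
  cth <- 1 - (1 / eps - 1) / a
  w <- eps + 1 / eps - (1 - cth^2)
  mu_oracle <- sum(w * eps) / sum(w)
  se <- stats::sd(s[, 1]) / sqrt(nrow(s))
  expect_lt(abs(mean(s[, 1]) - mu_oracle), 3 * se)
})

test_that("Compton scattering approaches the symmetric Thomson limit at low energy", {
  set.seed(12)
  s <- linacmc:::cpp_sample_compton(2e5, 0.001)
  fwd <- sum(s[, 3] < pi / 2)
  bwd <- sum(s[, 3] > pi / 2)
  # forward/backward counts equal within 3 sigma of a fair split
  expect_lt(abs(fwd - bwd), 3 * sqrt(nrow(s)))
})

test_that("bremsstrahlung sampler respects the kinematic bound and its moments", {
  set.seed(13)
  e0 <- 8.8; kmin <- 0.05
  s <- linacmc:::cpp_sample_brems(1e6, e0, kmin, 0.055)
  expect_true(all(s[, 1] <= e0 + 1e-12))
  expect_true(all(s[, 1] >= kmin - 1e-12))
  # quadrature of the implemented spectrum (1/k)(1 - k/E + 0.75 (k/E)^2)
  kk <- exp(seq(log(kmin), log(e0), length.out = 40001))
  f <- (1 - kk / e0 + 0.75 * (kk / e0)^2)   # density in log k
  mu_oracle <- sum(f * kk) / sum(f)
  se <- stats::sd(s[, 1]) / sqrt(nrow(s))
  expect_lt(abs(mean(s[, 1]) - mu_oracle), 3 * se)
  # angular factor: fraction of emissions inside the characteristic angle
  # against quadrature of p(theta) ~ theta/(1+(theta/tc)^2)^2
  tc <- 0.055
  th <- seq(0, 1.3, length.out = 200001)
  p <- th / (1 + (th / tc)^2)^2
  frac_oracle <- sum(p[th <= tc]) / sum(p)
  frac <- mean(s[, 2] <= tc)
  expect_lt(abs(frac - frac_oracle), 3 * sqrt(frac_oracle / nrow(s)))
})

test_that("a scatter-free diverging beam attenuates as exp(-mu z) with inverse square", {
  h <- fff7mv_head(10)
  model <- linacmc:::.engine_model(h, fff7mv_source(), run_config(),
                                   scoring_kerma(pdd_radius_cm = 1,
                                                 pdd_dz_mm = 10),
                                   source_mode = 2L, pp_energy = 2,
                                   pp_cone = 0.02, absorb_only = TRUE)
  model$run$air_on <- FALSE
  set.seed(3)
  res <- linacmc:::cpp_run_batch(model, 3e5)
  z <- (seq_len(40) - 0.5)
  mu <- attenuation_coefficient("water", 2)
  pred <- exp(-mu * z) * (100 / (100 + z))^2
  ratio <- (res$cyl / res$cyl[1]) / (pred / pred[1])
  expect_lt(max(abs(ratio - 1)), 0.02)
})
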