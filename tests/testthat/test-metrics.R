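# Dosimetric metrics on analytic fixtures with closed-form expectations.

test_that("D20/D10 interpolates at exactly 100 and 200 mm", {
  z <- seq(0.5, 300, 1)
  expect_equal(d20_d10(scan_curve(z, rep(5, length(z)), kind = "pdd")), 1.0)
  expect_equal(d20_d10(scan_curve(z, exp(-0.05 * z / 10), kind = "pdd")),
               exp(-0.5), tolerance = 1e-6)
  expect_error(d20_d10(scan_curve(1:50, 1:50, kind = "pdd")), "cover")
})

test_that("penumbra matches the error-function closed form", {
  s <- 5.5
  p <- flat_erf_profile(field_mm = 100, sigma_mm = s)
  # closed form: 20-80% width of a cumulative-normal edge
  expect_equal(penumbra(p, "left"), 2 * qnorm(0.8) * s, tolerance = 0.1 / 2)
  expect_equal(penumbra(p, "right"), 2 * qnorm(0.8) * s, tolerance = 0.1 / 2)
  # affine equivariance: doubling positions doubles the penumbra
  p2 <- scan_curve(p$position_mm * 2, p$dose, kind = "profile",
                   normalization = "cax")
  expect_equal(penumbra(p2, "both"), 2 * penumbra(p, "both"),
               tolerance = 0.02)
  # raw curves are rejected
  raw <- scan_curve(p$position_mm, p$dose, kind = "profile")
  expect_error(penumbra(raw), "normalize")
})

test_that("dosimetric field size finds the inflection separation", {
  p <- flat_erf_profile(field_mm = 100, sigma_mm = 4)
  expect_equal(dosimetric_field_size(p), 100, tolerance = 0.5)
  # translation equivariance of the inflection points
  sh <- scan_curve(p$position_mm,
                   approx(p$position_mm, p$dose, xout = p$position_mm - 3,
                          rule = 2)$y,
                   kind = "profile", normalization = "cax")
  ip <- inflection_points(sh)
  expect_equal(ip$I_R + ip$I_L, 6, tolerance = 0.3)  # both edges moved +3
  expect_equal(ip$I_R - ip$I_L, 100, tolerance = 0.5)
})

test_that("field size differs from the 50% width on a renormalized cone", {
  # on an FFF cone the 50% level sits outside the inflection points, so the
  # two statistics must not collapse onto each other
  p <- renormalize_fff(analytic_fff_profile()$profile)
  fs <- dosimetric_field_size(p)
  w50 <- linacmc:::.edge_crossing(p, 50, "right") -
    linacmc:::.edge_crossing(p, 50, "left")
  expect_gt(abs(fs - w50), 1)    # regression guard: not the same statistic
})

test_that("shoulder renormalization is idempotent and scale-invariant", {
  ref <- analytic_fff_profile()
  p <- ref$profile
  r1 <- renormalize_fff(p)
  r2 <- renormalize_fff(r1)
  expect_equal(r2$dose, r1$dose, tolerance = 1e-9)
  expect_equal(attr(r2, "scale_factor"), 1, tolerance = 1e-9)
  # invariance under uniform rescaling of the raw dose values
  pc <- scan_curve(p$position_mm, p$dose * 37.2, kind = "profile")
  rc <- renormalize_fff(pc)
  expect_equal(rc$dose, r1$dose, tolerance = 1e-9)
  # shoulder dose is 100% by construction
  sh <- attr(r1, "shoulder")
  expect_equal(mean(sh$dose_pct), 100, tolerance = 1e-9)
  # flat, structureless input has no shoulder
  flat <- scan_curve(seq(-50, 50), rep(100, 101), kind = "profile",
                     normalization = "cax")
  expect_error(renormalize_fff(flat), "inflection|penumbra")
})

test_that("unflatness is 1 for a flat profile and > 1 for a cone", {
  pf <- flat_erf_profile(100, 4)
  expect_equal(unflatness(pf), 1.0, tolerance = 0.01)
  cone <- renormalize_fff(analytic_fff_profile()$profile)
  expect_gt(unflatness(cone), 1.05)
  expect_error(unflatness(pf, field_size_mm = 500), "outside")
})

test_that("slope recovers a linear cone gradient exactly", {
  g <- 0.3   # %/mm on the normalized scale
  tp <- triangle_profile(g_per_mm = g, half_mm = 50)
  # slope is reported per cm
  expect_equal(profile_slope(tp, field_size_mm = 100), 10 * g,
               tolerance = 0.05)
  flat <- flat_erf_profile(100, 4)
  expect_equal(profile_slope(flat, field_size_mm = 100), 0,
               tolerance = 0.03)
})

test_that("peak position is zero for a centered cone and tracks translation", {
  tp <- triangle_profile(0.3, 50, shift_mm = 0)
  expect_equal(peak_position(tp, field_size_mm = 100), 0, tolerance = 0.05)
  sh <- triangle_profile(0.3, 50, shift_mm = 1)
  expect_equal(peak_position(sh, field_size_mm = 100), 1, tolerance = 0.25)
  flat <- flat_erf_profile(100, 4)
  expect_error(peak_position(flat, field_size_mm = 100), "degenerate")
})

test_that("symmetry is the maximum mirrored-dose variation", {
  even <- triangle_profile(0.3, 50)
  expect_equal(profile_symmetry(even, field_size_mm = 100), 0,
               tolerance = 1e-9)
  # one side scaled by 1.02 inside the field reads 2% at the field edge
  p <- flat_erf_profile(100, 4)
  d <- p$dose
  d[p$position_mm > 0] <- d[p$position_mm > 0] * 1.02
  pa <- scan_curve(p$position_mm, d, kind = "profile", normalization = "cax")
  expect_equal(profile_symmetry(pa, field_size_mm = 90), 2.0,
               tolerance = 0.1)
  # invariant under reflection
  pr <- scan_curve(p$position_mm, rev(d), kind = "profile",
                   normalization = "cax")
  expect_equal(profile_symmetry(pr, field_size_mm = 90),
               profile_symmetry(pa, field_size_mm = 90), tolerance = 1e-9)
})

test_that("curve comparison reports per-point and maximum differences", {
  z <- seq(0.5, 300, 1)
  a <- scan_curve(z, 100 * exp(-0.004 * z), kind = "pdd",
                  normalization = "dmax")
  expect_equal(compare_curves(a, a)$max_abs_diff, 0)
  b <- a; b$dose <- b$dose + 1
  cmp <- compare_curves(b, a)
  expect_equal(cmp$max_abs_diff, 1, tolerance = 1e-9)
  expect_equal(nrow(cmp$diffs), length(z))
  c2 <- scan_curve(400:500, rep(1, 101), kind = "pdd")
  expect_error(compare_curves(a, c2), "disjoint")
})

test_that("all profile metrics are invariant under raw rescaling", {
  p <- analytic_fff_profile()$profile
  raw1 <- scan_curve(p$position_mm, p$dose, kind = "profile")
  raw2 <- scan_curve(p$position_mm, p$dose * 0.037, kind = "profile")
  m1 <- profile_metrics(raw1, "fff")
  m2 <- profile_metrics(raw2, "fff")
  expect_equal(as.data.frame(m1[-1]), as.data.frame(m2[-1]),
               tolerance = 1e-9)
  expect_true(m1$field_size_mm ==
                m1$inflection_right_mm - m1$inflection_left_mm)
})
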