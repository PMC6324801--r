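# Scalar dosimetric statistics on depth-dose curves and lateral profiles:
# D20/D10, penumbra, dosimetric field size, unflatness, slope, peak position,
# symmetry, shoulder-point renormalization of FFF profiles, and curve
# comparison.

.require_normalized <- function(curve) {
  if (identical(attr(curve, "normalization"), "raw")) {
    stop("metric requires a normalized curve; apply normalize_curve() or ",
         "renormalize_fff() first", call. = FALSE)
  }
}

#' Depth-dose penetration ratio D20/D10
#'
#' Ratio of the central-axis dose at 20 cm depth to the dose at 10 cm depth,
#' by linear interpolation of the depth-dose curve. Works on raw or
#' normalized curves (the ratio is normalization-invariant).
#'
#' @param pdd A depth-dose [scan_curve()] covering 100-200 mm.
#' @return The dimensionless ratio.
#' @examples
#' z <- seq(0, 300, 1)
#' pdd <- scan_curve(z, exp(-0.05 * z / 10), kind = "pdd")
#' d20_d10(pdd)  # exp(-0.5)
#' @export
d20_d10 <- function(pdd) {
  if (min(pdd$position_mm) > 100 || max(pdd$position_mm) < 200) {
    stop("depth-dose curve must cover 100 mm and 200 mm depth",
         call. = FALSE)
  }
  v <- stats::approx(pdd$position_mm, pdd$dose, xout = c(100, 200))$y
  v[2] / v[1]
}

# Savitzky-Golay smoothed derivatives on a uniform grid
.sg_deriv <- function(y, dx, order = 1, window = 5, poly = 2) {
  if (length(y) < window + 2) stop("curve too short for smoothing",
                                   call. = FALSE)
  signal::sgolayfilt(y, p = poly, n = window, m = order, ts = dx)
}

# parabolic refinement of an extremum of a sampled function
.parabolic_peak <- function(x, y, i) {
  if (i <= 1 || i >= length(y)) return(x[i])
  d <- (y[i - 1] - 2 * y[i] + y[i + 1])
  if (abs(d) < 1e-300) return(x[i])
  x[i] + 0.5 * (x[i] - x[i - 1]) * (y[i - 1] - y[i + 1]) / d
}

#' Profile inflection points
#'
#' Positions of the left and right penumbral inflection points, located at
#' the extrema of a Savitzky-Golay smoothed first derivative with parabolic
#' refinement.
#'
#' @param profile A lateral-profile [scan_curve()].
#' @param window,poly Smoothing window (points) and polynomial order.
#' @return A list with `I_L` and `I_R` (mm).
#' @export
inflection_points <- function(profile, window = 5, poly = 2) {
  x <- profile$position_mm
  y <- profile$dose
  if (max(y) - min(y) < 0.2 * max(y)) {
    stop("no inflection point found: profile has no resolved penumbra",
         call. = FALSE)
  }
  dx <- stats::median(diff(x))
  d1 <- .sg_deriv(y, dx, order = 1, window = window, poly = poly)
  left <- which(x < 0)
  right <- which(x > 0)
  il <- left[which.max(d1[left])]
  ir <- right[which.min(d1[right])]
  if (il %in% c(left[1], left[length(left)]) && length(left) > 3 &&
      d1[il] <= 0) {
    stop("no inflection point found on the left side", call. = FALSE)
  }
  list(I_L = .parabolic_peak(x, d1, il), I_R = .parabolic_peak(x, d1, ir))
}

#' Dosimetric field size
#'
#' Distance between the right and left penumbral inflection points.
#'
#' @inheritParams inflection_points
#' @return Field size in mm.
#' @export
dosimetric_field_size <- function(profile, window = 5, poly = 2) {
  ip <- inflection_points(profile, window, poly)
  ip$I_R - ip$I_L
}

# crossing of `level` on one side of the profile, by monotone linear
# interpolation within the penumbral window
.edge_crossing <- function(profile, level, side) {
  x <- profile$position_mm
  y <- profile$dose
  sgn <- if (side == "right") 1 else -1
  sel <- which(sgn * x >= 0)
  xs <- sgn * x[sel]
  o <- order(xs)
  xs <- xs[o]; ys <- y[sel][o]
  # innermost index still at/above 50%
  i50 <- suppressWarnings(max(which(ys >= 50)))
  if (!is.finite(i50)) stop("profile never reaches 50% on the ", side,
                            " side", call. = FALSE)
  if (level <= ys[i50]) {
    j <- i50
    while (j < length(ys) && ys[j + 1] >= level) j <- j + 1
    if (j >= length(ys)) stop("level ", level, "% not crossed on the ",
                              side, " side", call. = FALSE)
    f <- (ys[j] - level) / (ys[j] - ys[j + 1])
    return(sgn * (xs[j] + f * (xs[j + 1] - xs[j])))
  }
  j <- i50
  while (j > 1 && ys[j - 1] < level) j <- j - 1
  if (j <= 1 && ys[1] < level) stop("level ", level, "% not crossed on the ",
                                    side, " side", call. = FALSE)
  f <- (level - ys[j]) / (ys[j - 1] - ys[j])
  sgn * (xs[j] + f * (xs[j - 1] - xs[j]))
}

#' Penumbral width
#'
#' Lateral distance between the 20% and 80% levels of the normalized
#' profile on one side.
#'
#' @param profile A normalized lateral-profile [scan_curve()].
#' @param side `"left"`, `"right"`, or `"both"` (mean of the two).
#' @return Penumbra in mm.
#' @export
penumbra <- function(profile, side = c("both", "left", "right")) {
  side <- match.arg(side)
  .require_normalized(profile)
  one <- function(s) {
    abs(.edge_crossing(profile, 80, s) - .edge_crossing(profile, 20, s))
  }
  switch(side,
         left = one("left"),
         right = one("right"),
         both = mean(c(one("left"), one("right"))))
}

#' Shoulder-point renormalization of an FFF profile
#'
#' Flattening-filter-free profiles have no flat top, so flat-beam metrics
#' need a renormalization: each penumbral shoulder is located where the
#' smoothed second derivative is largest in magnitude between the central
#' peak region and the penumbral inflection point, and the profile is
#' rescaled so the mean shoulder dose is 100%. The operation is idempotent.
#'
#' @param profile A lateral-profile [scan_curve()] with a single central
#'   peak (renormalizes from any prior normalization state).
#' @param window,poly Smoothing parameters for the derivatives.
#' @return The renormalized curve (normalization `"fff_shoulder"`), with
#'   attributes `shoulder` (positions/doses) and `scale_factor`.
#' @export
renormalize_fff <- function(profile, window = 5, poly = 2) {
  # work in a provisional cax-normalized scale for window definitions
  base <- profile
  cax <- stats::approx(base$position_mm, base$dose, xout = 0)$y
  if (!isTRUE(cax > 0)) stop("profile has no central-axis dose",
                             call. = FALSE)
  tmp <- base; tmp$dose <- 100 * base$dose / cax
  attr(tmp, "normalization") <- "cax"
  ip <- inflection_points(tmp, window, poly)
  x <- tmp$position_mm
  dx <- stats::median(diff(x))
  d2 <- .sg_deriv(tmp$dose, dx, order = 2, window = window, poly = poly)
  shoulder_side <- function(I_s, sgn) {
    # search between 15% and 90% of the way from the axis to the inflection
    win <- which(sgn * x >= 0.15 * abs(I_s) & sgn * x <= 0.90 * abs(I_s))
    if (length(win) < 3) stop("no shoulder window on one side",
                              call. = FALSE)
    i <- win[which.max(abs(d2[win]))]
    xp <- .parabolic_peak(x, abs(d2), i)
    list(x = xp, dose = stats::approx(x, base$dose, xout = xp)$y)
  }
  sl <- shoulder_side(ip$I_L, -1)
  sr <- shoulder_side(ip$I_R, 1)
  ref <- mean(c(sl$dose, sr$dose))
  out <- base
  out$dose <- 100 * base$dose / ref
  out <- .curve_attr_keep(out, base, normalization = "fff_shoulder")
  attr(out, "shoulder") <- tibble::tibble(
    side = c("left", "right"), position_mm = c(sl$x, sr$x),
    dose_pct = 100 * c(sl$dose, sr$dose) / ref)
  attr(out, "scale_factor") <- 100 / ref
  out
}

#' Unflatness of an FFF profile
#'
#' Central-axis dose divided by the mean off-axis dose at 80% of the half
#' field size (left/right averaged).
#'
#' @param profile A normalized profile (shoulder-renormalized for FFF).
#' @param field_size_mm Dosimetric field size; computed from the inflection
#'   points when omitted.
#' @return The dimensionless unflatness ratio (1 for a flat profile).
#' @export
unflatness <- function(profile, field_size_mm = NULL) {
  .require_normalized(profile)
  fs <- field_size_mm %||% dosimetric_field_size(profile)
  xo <- 0.8 * fs / 2
  rng <- range(profile$position_mm)
  if (-xo < rng[1] || xo > rng[2]) {
    stop("80% field-size points outside the profile", call. = FALSE)
  }
  v <- stats::approx(profile$position_mm, profile$dose,
                     xout = c(-xo, 0, xo))$y
  v[2] / mean(v[c(1, 3)])
}

#' Profile slope
#'
#' Average of the absolute left/right slopes of the cone of an FFF profile,
#' evaluated between the points at 1/3 and 2/3 of the half-profile width.
#' Reported per cm of off-axis distance (%/cm).
#'
#' @inheritParams unflatness
#' @return Mean absolute slope (%/cm).
#' @export
profile_slope <- function(profile, field_size_mm = NULL) {
  .require_normalized(profile)
  fs <- field_size_mm %||% dosimetric_field_size(profile)
  half <- fs / 2
  one <- function(sgn) {
    x1 <- sgn * 2 / 3 * half; x2 <- sgn * 1 / 3 * half
    v <- stats::approx(profile$position_mm, profile$dose,
                       xout = c(x1, x2))$y
    (v[1] - v[2]) / ((x1 - x2) / 10)
  }
  mean(abs(c(one(-1), one(1))))
}

#' Peak position of an FFF profile
#'
#' Intersection of straight lines fitted to the two cone flanks (the 1/3 to
#' 2/3 half-profile windows): `(I_R - I_L) / (S_L - S_R)` with I the fitted
#' intercepts and S the fitted slopes. Zero for a centered symmetric cone; a
#' profile translated by +d reports +d.
#'
#' @inheritParams unflatness
#' @return Peak position in mm.
#' @export
peak_position <- function(profile, field_size_mm = NULL) {
  .require_normalized(profile)
  fs <- field_size_mm %||% dosimetric_field_size(profile)
  half <- fs / 2
  fit <- function(sgn) {
    sel <- which(sgn * profile$position_mm >= half / 3 &
                 sgn * profile$position_mm <= 2 * half / 3)
    if (length(sel) < 2) stop("too few points in the slope window",
                              call. = FALSE)
    stats::coef(stats::lm(dose ~ position_mm, data = profile[sel, ]))
  }
  cl <- fit(-1); cr <- fit(1)
  if (abs(cl[2] - cr[2]) < 1e-4) {
    stop("degenerate geometry: equal side slopes", call. = FALSE)
  }
  unname((cr[1] - cl[1]) / (cl[2] - cr[2]))
}

#' Profile symmetry (maximum variation)
#'
#' Maximum absolute difference between doses at mirrored positions inside
#' the dosimetric field, in percent points.
#'
#' @inheritParams unflatness
#' @return Symmetry in percent points (0 for an even profile).
#' @export
profile_symmetry <- function(profile, field_size_mm = NULL) {
  .require_normalized(profile)
  fs <- field_size_mm %||% dosimetric_field_size(profile)
  xmax <- min(fs / 2, max(profile$position_mm), -min(profile$position_mm))
  xg <- seq(0, xmax * 0.999, by = stats::median(diff(profile$position_mm)))
  dp <- stats::approx(profile$position_mm, profile$dose, xout = xg)$y
  dm <- stats::approx(profile$position_mm, profile$dose, xout = -xg)$y
  max(abs(dp - dm))
}

#' Compare two scan curves
#'
#' Interpolates the reference curve onto the evaluation grid of the first
#' curve (over the overlapping range) and reports per-point absolute
#' differences and their maximum, in the units of the curves (percent points
#' for normalized curves).
#'
#' @param sim,ref Two [scan_curve()]s on overlapping position ranges.
#' @return A list with `max_abs_diff` and a `diffs` tibble.
#' @export
compare_curves <- function(sim, ref) {
  lo <- max(min(sim$position_mm), min(ref$position_mm))
  hi <- min(max(sim$position_mm), max(ref$position_mm))
  if (lo >= hi) stop("curves have disjoint position ranges", call. = FALSE)
  sel <- sim$position_mm >= lo & sim$position_mm <= hi
  rv <- stats::approx(ref$position_mm, ref$dose,
                      xout = sim$position_mm[sel])$y
  sv <- sim$dose[sel]
  d <- tibble::tibble(position_mm = sim$position_mm[sel],
                      sim = sv, ref = rv, abs_diff = abs(sv - rv))
  list(max_abs_diff = max(d$abs_diff), diffs = d)
}

#' All profile metrics in one row
#'
#' Convenience wrapper: renormalizes (FFF) or CAX-normalizes (flat) a raw
#' profile and evaluates every profile statistic.
#'
#' @param profile A lateral-profile [scan_curve()].
#' @param mode `"fff"` (shoulder renormalization) or `"flat"`.
#' @return One-row tibble of metrics.
#' @export
profile_metrics <- function(profile, mode = c("fff", "flat")) {
  mode <- match.arg(mode)
  p <- if (mode == "fff") renormalize_fff(profile) else
    normalize_curve(profile, "cax")
  ip <- inflection_points(p)
  fs <- ip$I_R - ip$I_L
  tibble::tibble(
    mode = mode,
    penumbra_left_mm = penumbra(p, "left"),
    penumbra_right_mm = penumbra(p, "right"),
    field_size_mm = fs,
    inflection_left_mm = ip$I_L,
    inflection_right_mm = ip$I_R,
    unflatness = unflatness(p, fs),
    slope_pct_per_cm = profile_slope(p, fs),
    peak_position_mm = peak_position(p, fs),
    symmetry_pct = profile_symmetry(p, fs)
  )
}
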