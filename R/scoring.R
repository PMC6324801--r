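# Dose containers and curve extraction: voxel dose grids with per-batch
# uncertainty, scan curves (depth dose / lateral profile), surface dose.

#' Scan curve (depth-dose or lateral profile)
#'
#' A tibble of sampled dose values along a line, the common currency of the
#' analysis pipeline. Positions are strictly increasing; the normalization
#' state is tracked as an attribute (`"raw"`, `"dmax"`, `"cax"`,
#' `"fff_shoulder"`).
#'
#' @param position_mm Positions (depth for a PDD, off-axis distance for a
#'   profile), mm, strictly increasing.
#' @param dose Dose values (Gy/primary when raw, percent when normalized).
#' @param kind `"pdd"` or `"profile"`.
#' @param normalization Normalization state.
#' @param unc_pct Optional per-point relative uncertainty (%).
#' @param meta Optional metadata list.
#' @return A `scan_curve` tibble.
#' @export
scan_curve <- function(position_mm, dose, kind = c("pdd", "profile"),
                       normalization = "raw", unc_pct = NULL, meta = list()) {
  kind <- match.arg(kind)
  if (any(diff(position_mm) <= 0)) {
    stop("scan positions must be strictly increasing", call. = FALSE)
  }
  x <- tibble::tibble(position_mm = as.double(position_mm),
                      dose = as.double(dose))
  if (!is.null(unc_pct)) x$unc_pct <- as.double(unc_pct)
  attr(x, "kind") <- kind
  attr(x, "normalization") <- normalization
  attr(x, "meta") <- meta
  class(x) <- c("scan_curve", class(x))
  x
}

.curve_attr_keep <- function(new, old, normalization = NULL) {
  attr(new, "kind") <- attr(old, "kind")
  attr(new, "normalization") <- normalization %||% attr(old, "normalization")
  attr(new, "meta") <- attr(old, "meta")
  if (!inherits(new, "scan_curve")) class(new) <- c("scan_curve", class(new))
  new
}

#' Normalize a scan curve
#'
#' Depth-dose curves are normalized to 100% at the depth of maximum dose;
#' profiles of flattened beams to their central-axis value. FFF profiles
#' use the shoulder-point renormalization instead, see [renormalize_fff()].
#'
#' @param curve A [scan_curve()].
#' @param method `"max"` (100% at the curve maximum) or `"cax"` (100% at
#'   position 0).
#' @return The normalized curve (normalization attribute `"dmax"` or
#'   `"cax"`).
#' @export
normalize_curve <- function(curve, method = c("max", "cax")) {
  method <- match.arg(method)
  ref <- if (method == "max") max(curve$dose) else
    stats::approx(curve$position_mm, curve$dose, xout = 0)$y
  if (!isTRUE(ref > 0)) stop("cannot normalize a zero curve", call. = FALSE)
  out <- curve
  out$dose <- 100 * curve$dose / ref
  .curve_attr_keep(out, curve,
                   normalization = if (method == "max") "dmax" else "cax")
}

# ---------------------------------------------------------------------------
# dose grid

#' Voxelised dose grid
#'
#' Wraps per-batch energy deposition on a regular voxel grid and converts to
#' dose per primary electron. Constructed by [run_simulation()]; the
#' constructor is exported for building synthetic grids in analyses/tests.
#'
#' @param batch_edep 4-D array (nx, ny, nz, n_batches) of weighted energy
#'   deposits (MeV), or a 3-D array for a single batch.
#' @param voxel_mm Voxel edge length (mm).
#' @param origin_cm Coordinates (x, y, z) of the grid corner (cm); z = 100 is
#'   the phantom surface.
#' @param n_histories Number of primary histories the deposits correspond to.
#' @return A `dose_grid` object.
#' @export
new_dose_grid <- function(batch_edep, voxel_mm, origin_cm = c(-20, -20, 100),
                          n_histories = 1) {
  if (length(dim(batch_edep)) == 3) {
    batch_edep <- array(batch_edep, c(dim(batch_edep), 1))
  }
  stopifnot(length(dim(batch_edep)) == 4, voxel_mm > 0)
  structure(
    list(batch_edep = batch_edep,
         voxel_mm = voxel_mm,
         origin_cm = origin_cm,
         dims = dim(batch_edep)[1:3],
         n_batches = dim(batch_edep)[4],
         n_histories = n_histories),
    class = "dose_grid"
  )
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> ", paste(x$dims, collapse = "x"), " voxels of ",
      x$voxel_mm, " mm, ", x$n_batches, " batches, ",
      format(x$n_histories, big.mark = ","), " histories\n", sep = "")
  invisible(x)
}

#' Dose array in Gy per primary
#' @param grid A [new_dose_grid()] object.
#' @return 3-D array of dose (Gy/primary).
#' @export
dose_array <- function(grid) {
  mass_kg <- (grid$voxel_mm / 10)^3 / 1000   # water
  apply(grid$batch_edep, 1:3, sum) / grid$n_histories * MEV_TO_J / mass_kg
}

#' @export
as_tibble.dose_grid <- function(x, ...) {
  d <- dose_array(x)
  dm <- x$dims
  vox <- x$voxel_mm / 10
  tibble::tibble(
    x_cm = x$origin_cm[1] + (rep(seq_len(dm[1]), times = dm[2] * dm[3]) - 0.5) * vox,
    y_cm = x$origin_cm[2] + (rep(rep(seq_len(dm[2]), each = dm[1]), times = dm[3]) - 0.5) * vox,
    z_cm = x$origin_cm[3] + (rep(seq_len(dm[3]), each = dm[1] * dm[2]) - 0.5) * vox,
    dose = as.vector(d)
  )
}

# voxel column index nearest a coordinate; ties broken toward +
.col_index <- function(grid, coord_cm, axis) {
  vox <- grid$voxel_mm / 10
  centers <- grid$origin_cm[axis] + (seq_len(grid$dims[axis]) - 0.5) * vox
  d <- abs(centers - coord_cm)
  idx <- which(d == min(d))
  idx[length(idx)]
}

#' Extract a depth-dose curve from a dose grid
#'
#' Returns the dose versus depth along the vertical voxel column nearest the
#' (possibly shifted) beam axis. Off-axis depth doses follow the convention
#' that an off-axis distance of `n` cm means an `n` cm shift along both x
#' and y.
#'
#' @param grid A [new_dose_grid()] object.
#' @param lateral_offset_cm Off-axis distance (cm), applied to both axes.
#' @return A raw [scan_curve()] (Gy/primary vs depth in mm).
#' @export
extract_pdd <- function(grid, lateral_offset_cm = 0) {
  vox <- grid$voxel_mm / 10
  xmax <- grid$origin_cm[1] + grid$dims[1] * vox
  if (lateral_offset_cm < grid$origin_cm[1] || lateral_offset_cm > xmax) {
    stop("lateral offset outside the scored grid", call. = FALSE)
  }
  ix <- .col_index(grid, lateral_offset_cm, 1)
  iy <- .col_index(grid, lateral_offset_cm, 2)
  col <- grid$batch_edep[ix, iy, , , drop = FALSE]
  col <- array(col, c(grid$dims[3], grid$n_batches))
  mass_kg <- (vox)^3 / 1000
  dose <- rowSums(col) / grid$n_histories * MEV_TO_J / mass_kg
  depth <- (seq_len(grid$dims[3]) - 0.5) * grid$voxel_mm +
    (grid$origin_cm[3] - 100) * 10
  scan_curve(depth, dose, kind = "pdd",
             unc_pct = if (grid$n_batches >= 2) .batch_rel_se(col),
             meta = list(lateral_offset_cm = lateral_offset_cm))
}

#' Extract a lateral profile from a dose grid
#'
#' Dose along a single voxel row at the layer containing `depth_cm`
#' (optionally averaged over `n_avg` adjacent rows in the perpendicular
#' direction to reduce variance).
#'
#' @param grid A [new_dose_grid()] object.
#' @param depth_cm Depth of the profile (cm).
#' @param axis `"x"` or `"y"`.
#' @param n_avg Number of perpendicular rows averaged (odd; default 1, the
#'   single-row convention).
#' @return A raw [scan_curve()].
#' @export
extract_profile <- function(grid, depth_cm = 10, axis = c("x", "y"),
                            n_avg = 1) {
  axis <- match.arg(axis)
  vox <- grid$voxel_mm / 10
  if (depth_cm < 0 || depth_cm > grid$dims[3] * vox + (grid$origin_cm[3] - 100)) {
    stop("depth outside the scored grid", call. = FALSE)
  }
  iz <- .col_index(grid, 100 + depth_cm, 3)
  ic <- .col_index(grid, 0, if (axis == "x") 2 else 1)
  half <- (n_avg - 1) %/% 2
  sel <- pmax(1, ic - half):pmin(grid$dims[if (axis == "x") 2 else 1], ic + half)
  if (axis == "x") {
    sl <- grid$batch_edep[, sel, iz, , drop = FALSE]
    m <- apply(sl, c(1, 4), mean)
    pos <- (grid$origin_cm[1] + (seq_len(grid$dims[1]) - 0.5) * vox) * 10
  } else {
    sl <- grid$batch_edep[sel, , iz, , drop = FALSE]
    m <- apply(sl, c(2, 4), mean)
    pos <- (grid$origin_cm[2] + (seq_len(grid$dims[2]) - 0.5) * vox) * 10
  }
  mass_kg <- vox^3 / 1000
  dose <- rowSums(m) / grid$n_histories * MEV_TO_J / mass_kg
  scan_curve(pos, dose, kind = "profile",
             unc_pct = if (grid$n_batches >= 2) .batch_rel_se(m),
             meta = list(depth_cm = depth_cm, axis = axis, n_avg = n_avg))
}

#' Surface dose relative to the dose maximum
#'
#' Central-axis dose in the first millimetre of water (the air-skin
#' boundary) as a percentage of the central-axis maximum. Requires a 1 mm
#' grid: 5 mm voxels average over the steep buildup gradient and are not
#' comparable.
#'
#' @param grid_1mm A [new_dose_grid()] with 1 mm voxels.
#' @return Surface dose in percent of the CAX maximum.
#' @export
surface_dose <- function(grid_1mm) {
  if (!isTRUE(all.equal(grid_1mm$voxel_mm, 1))) {
    stop("surface dose is defined on a 1 mm grid (got ",
         grid_1mm$voxel_mm, " mm voxels)", call. = FALSE)
  }
  pdd <- extract_pdd(grid_1mm)
  100 * pdd$dose[1] / max(pdd$dose)
}

#' Per-voxel statistical uncertainty
#'
#' Relative standard error of the mean over batch sub-sums, in percent.
#'
#' @param grid A [new_dose_grid()] with at least two batches.
#' @return Array (same dims as the grid) of relative standard errors (%).
#' @export
estimate_uncertainty <- function(grid) {
  if (grid$n_batches < 2) {
    stop("uncertainty estimation needs at least 2 batches", call. = FALSE)
  }
  mu <- apply(grid$batch_edep, 1:3, mean)
  s <- apply(grid$batch_edep, 1:3, stats::sd) / sqrt(grid$n_batches)
  out <- array(0, dim(mu))
  pos <- mu > 0
  out[pos] <- 100 * s[pos] / mu[pos]
  out
}

# ---------------------------------------------------------------------------
# serialization

#' Save / load a dose grid
#'
#' The grid is stored as a documented plain list (datasets `dose`,
#' `batch_edep`, and metadata) so it can be reloaded or inspected without
#' the package.
#' @param grid A [new_dose_grid()] object.
#' @param path Output path (`.rds`).
#' @export
write_dose_grid <- function(grid, path) {
  saveRDS(list(format = "linacmc-dose-grid", version = 1L,
               voxel_mm = grid$voxel_mm, origin_cm = grid$origin_cm,
               n_histories = grid$n_histories,
               batch_edep = grid$batch_edep,
               dose = dose_array(grid)),
          path)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path) {
  x <- readRDS(path)
  stopifnot(identical(x$format, "linacmc-dose-grid"))
  new_dose_grid(x$batch_edep, x$voxel_mm, x$origin_cm, x$n_histories)
}

#' Write / read a scan curve in the water-tank CSV dialect
#'
#' Two data columns (`position_mm`, `dose`) with a small commented header
#' recording the curve kind and normalization state.
#' @param curve A [scan_curve()].
#' @param path CSV path.
#' @export
write_scan_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# linacmc scan curve; kind=%s; normalization=%s",
                     attr(curve, "kind"), attr(curve, "normalization")), con)
  utils::write.csv(as.data.frame(curve)[c("position_mm", "dose")], con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_scan_curve
#' @export
read_scan_curve <- function(path) {
  hdr <- readLines(path, n = 1)
  kind <- sub(".*kind=([a-z]+);.*", "\\1", hdr)
  norm <- sub(".*normalization=([a-z_]+).*", "\\1", hdr)
  if (!kind %in% c("pdd", "profile")) kind <- "pdd"
  if (!nzchar(norm)) norm <- "raw"
  d <- utils::read.csv(path, comment.char = "#")
  scan_curve(d$position_mm, d$dose, kind = kind, normalization = norm)
}
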