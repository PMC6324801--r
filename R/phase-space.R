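# Phase-space files: compact binary format (.bpsf), reader/writer with
# integrity checks, and recycling semantics for the virtual-source workflow.
#
# Binary layout (little-endian):
#   bytes 0-3   magic "BPSF"
#   int32       format version (1)
#   double      plane z (cm)
#   double      n_original_histories
#   double      n_records
#   double x3   source (mean energy, sigma, spot fwhm)
#   double      header checksum (sum of the six doubles above)
#   n x 8 dbl   records: kind (0/1/2), energy MeV, x mm, y mm, u, v, w, weight
#   double      record checksum (sum of all energies)

.PSF_KINDS <- c("photon", "electron", "positron")

#' Phase-space object
#'
#' A stored list of particle states crossing a plane above the jaws,
#' reusable as a particle source ("virtual source model").
#'
#' @param records Numeric matrix with 8 columns (kind 0/1/2, energy, x mm,
#'   y mm, direction cosines u/v/w, weight) or a tibble with those fields.
#' @param plane_z Capture-plane z (cm).
#' @param n_original_histories Number of primary histories that produced the
#'   records.
#' @param source Optional [source_config()] recorded in the header.
#' @return A `phase_space` object.
#' @export
new_phase_space <- function(records, plane_z, n_original_histories,
                            source = NULL) {
  if (is.data.frame(records)) {
    records <- cbind(match(records$kind, .PSF_KINDS) - 1, records$energy,
                     records$x_mm, records$y_mm, records$u, records$v,
                     records$w, records$weight)
  }
  records <- matrix(as.double(records), ncol = 8,
                    dimnames = list(NULL, c("kind", "energy", "x_mm", "y_mm",
                                            "u", "v", "w", "weight")))
  if (nrow(records) > 0) {
    if (any(records[, "energy"] <= 0)) stop("PSF energies must be positive",
                                            call. = FALSE)
    if (any(records[, "w"] <= 0)) stop("PSF records must travel downward ",
                                       "(w > 0)", call. = FALSE)
  }
  structure(
    list(header = list(version = 1L, plane_z = plane_z,
                       n_original_histories = n_original_histories,
                       n_records = nrow(records),
                       source_mean_energy = source$mean_energy %||% NA_real_,
                       source_sigma = source$energy_spread_sigma %||% NA_real_,
                       source_spot_fwhm = source$spot_fwhm_mm %||% NA_real_),
         records = records),
    class = "phase_space"
  )
}

#' @export
print.phase_space <- function(x, ...) {
  cat("<phase_space> ", x$header$n_records, " records at z=",
      x$header$plane_z, " cm from ",
      format(x$header$n_original_histories, big.mark = ","),
      " histories\n", sep = "")
  invisible(x)
}

.psf_records_matrix <- function(psf) psf$records

#' Write / read a phase-space file
#'
#' Lossless round trip of all particle fields in the documented `.bpsf`
#' little-endian binary layout; the header and a record checksum are
#' validated on read, and corruption errors name the failing byte offset.
#'
#' @param psf A [new_phase_space()] object.
#' @param path File path (`.bpsf`).
#' @export
write_psf <- function(psf, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BPSF"), con)
  writeBin(1L, con, size = 4, endian = "little")
  h <- psf$header
  hd <- c(h$plane_z, h$n_original_histories, as.double(h$n_records),
          h$source_mean_energy, h$source_sigma, h$source_spot_fwhm)
  hd[is.na(hd)] <- -1
  writeBin(hd, con, size = 8, endian = "little")
  writeBin(sum(hd), con, size = 8, endian = "little")
  if (nrow(psf$records) > 0) {
    writeBin(as.vector(t(psf$records)), con, size = 8, endian = "little")
  }
  writeBin(sum(psf$records[, "energy"]) + 0, con, size = 8,
           endian = "little")
  invisible(path)
}

#' @rdname write_psf
#' @export
read_psf <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, charToRaw("BPSF"))) {
    stop("not a BPSF file: bad magic at byte offset 0", call. = FALSE)
  }
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ver != 1L) stop("unsupported BPSF version at byte offset 4",
                      call. = FALSE)
  hd <- readBin(con, "double", 6, size = 8, endian = "little")
  chk <- readBin(con, "double", 1, size = 8, endian = "little")
  if (!isTRUE(all.equal(sum(hd), chk))) {
    stop("corrupt header: checksum mismatch at byte offset 56",
         call. = FALSE)
  }
  n_rec <- hd[3]
  expected <- 4 + 4 + 7 * 8 + n_rec * 8 * 8 + 8
  if (sz != expected) {
    stop("truncated or corrupt file: expected ", expected, " bytes for ",
         n_rec, " records, found ", sz, " (records start at byte offset 64)",
         call. = FALSE)
  }
  rec <- matrix(readBin(con, "double", n_rec * 8, size = 8,
                        endian = "little"),
                ncol = 8, byrow = TRUE)
  rchk <- readBin(con, "double", 1, size = 8, endian = "little")
  esum <- if (n_rec > 0) sum(rec[, 2]) else 0
  if (!isTRUE(all.equal(esum, rchk))) {
    stop("corrupt records: energy checksum mismatch at byte offset ",
         64 + n_rec * 64, call. = FALSE)
  }
  src <- NULL
  if (hd[4] > 0) src <- source_config(hd[4], max(hd[5], 0), max(hd[6], 0.1))
  out <- new_phase_space(rec, plane_z = hd[1], n_original_histories = hd[2],
                         source = src)
  out
}

#' Recycle a phase space into a particle stream
#'
#' Emits every record `factor` times; for `factor > 1` each copy receives an
#' independent uniform azimuthal rotation about the central axis (valid for
#' capture planes above the jaws, where the head is rotationally symmetric —
#' asserted). The equivalent-history count is
#' `n_original_histories * factor`.
#'
#' @param psf A [new_phase_space()] object with plane above the jaws.
#' @param factor Recycling factor (>= 1).
#' @param seed Seed for the azimuthal rotations.
#' @return A particle tibble with attribute `equivalent_histories`.
#' @export
recycle <- function(psf, factor, seed = 1) {
  stopifnot(factor >= 1)
  if (psf$header$plane_z > 30) {
    stop("recycling rotation is only valid for capture planes above the ",
         "jaws (plane z = ", psf$header$plane_z, " cm)", call. = FALSE)
  }
  rec <- psf$records
  n <- nrow(rec)
  out <- rec[rep(seq_len(n), times = factor), , drop = FALSE]
  if (factor > 1 && n > 0) {
    set.seed(seed)
    phi <- stats::runif(nrow(out), 0, 2 * pi)
    cp <- cos(phi); sp <- sin(phi)
    x <- cp * out[, "x_mm"] - sp * out[, "y_mm"]
    y <- sp * out[, "x_mm"] + cp * out[, "y_mm"]
    u <- cp * out[, "u"] - sp * out[, "v"]
    v <- sp * out[, "u"] + cp * out[, "v"]
    out[, "x_mm"] <- x; out[, "y_mm"] <- y
    out[, "u"] <- u; out[, "v"] <- v
  }
  res <- tibble::tibble(
    kind = .PSF_KINDS[out[, "kind"] + 1],
    energy = out[, "energy"],
    x_mm = out[, "x_mm"], y_mm = out[, "y_mm"],
    u = out[, "u"], v = out[, "v"], w = out[, "w"],
    weight = out[, "weight"]
  )
  attr(res, "equivalent_histories") <-
    psf$header$n_original_histories * factor
  res
}

#' Summarise a phase-space file
#'
#' Prints the header and a per-kind fluence/spectrum summary.
#' @param x A `phase_space` object or a `.bpsf` path.
#' @return (Invisibly) a summary tibble.
#' @export
psf_info <- function(x) {
  if (is.character(x)) x <- read_psf(x)
  print(x)
  rec <- x$records
  summ <- dplyr::bind_rows(lapply(0:2, function(k) {
    sel <- rec[, "kind"] == k
    if (!any(sel)) return(NULL)
    tibble::tibble(kind = .PSF_KINDS[k + 1],
                   n = sum(sel),
                   weight = sum(rec[sel, "weight"]),
                   mean_energy = sum(rec[sel, "weight"] *
                                       rec[sel, "energy"]) /
                     sum(rec[sel, "weight"]))
  }))
  print(summ)
  invisible(summ)
}
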