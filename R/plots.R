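# ggplot2 display methods for curves, spectra, dose grids and tuning
# results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a scan curve
#'
#' @param object A [scan_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scan_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  xl <- if (identical(kind, "pdd")) "depth (mm)" else "off-axis position (mm)"
  norm <- attr(object, "normalization")
  yl <- if (identical(norm, "raw")) "dose (Gy/primary)" else "dose (%)"
  ggplot2::ggplot(object, ggplot2::aes(.data$position_mm, .data$dose)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = xl, y = yl) +
    ggplot2::theme_minimal()
}

#' Plot a fluence spectrum
#'
#' @param object A [spectrum_histogram()].
#' @param normalize Rescale to 100% at the modal bin.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_histogram <- function(object, normalize = TRUE, ...) {
  s <- if (normalize) normalize_spectrum(object) else object
  ggplot2::ggplot(s, ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                                  y = .data$fluence)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "energy (MeV)",
                  y = if (normalize) "fluence (% of max)" else
                    "fluence / primary") +
    ggplot2::theme_minimal()
}

#' Plot the central slice of a dose grid
#'
#' @param object A [new_dose_grid()].
#' @param ... Unused.
#' @return A ggplot (x-z dose map through the beam axis).
#' @export
autoplot.dose_grid <- function(object, ...) {
  d <- as_tibble(object)
  iy <- .col_index(object, 0, 2)
  vox <- object$voxel_mm / 10
  yc <- object$origin_cm[2] + (iy - 0.5) * vox
  sl <- d[abs(d$y_cm - yc) < vox / 2, ]
  ggplot2::ggplot(sl, ggplot2::aes(.data$x_cm, .data$z_cm,
                                   fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "Gy/primary") +
    ggplot2::labs(x = "x (cm)", y = "z (cm, 100 = surface)") +
    ggplot2::theme_minimal()
}

#' Plot a tuning objective landscape
#'
#' @param object A `tuning_result` from [tune_source()].
#' @param ... Unused.
#' @return A ggplot: stage-1 objective vs mean energy and stage-2 objective
#'   vs spot FWHM.
#' @export
autoplot.tuning_result <- function(object, ...) {
  tab <- object$table
  tab$panel <- ifelse(tab$stage == 1, "stage 1: mean energy (MeV)",
                      "stage 2: spot FWHM (mm)")
  tab$xval <- ifelse(tab$stage == 1, tab$mean_energy, tab$fwhm)
  ggplot2::ggplot(tab, ggplot2::aes(.data$xval, .data$objective)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "max |diff| (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
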