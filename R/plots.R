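#' Plot a kinetic trajectory
#'
#' Log-scale concentration traces of the non-trivial species.
#'
#' @param object A `kinetic_trajectory`.
#' @param species Species to show (default: all with nonzero maximum).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kinetic_trajectory <- function(object, species = NULL, ...) {
  long <- tidy(object)
  if (is.null(species)) {
    keep <- dplyr::summarise(dplyr::group_by(long, .data$species),
                             mx = max(.data$concentration_M), .groups = "drop")
    species <- keep$species[keep$mx > 0]
  }
  long <- dplyr::filter(long, .data$species %in% !!species,
                        .data$concentration_M > 0)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s / 60,
                                     .data$concentration_M,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (min)", y = "concentration (M)",
                  colour = "species")
}

#' Plot a relaxation curve with an optional fit
#'
#' @param object A `relaxation_curve`.
#' @param fit Optional `biexp_fit` overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relaxation_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$tau_us, .data$pl)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dark time (us)", y = "integrated PL (counts)")
  if (!is.null(fit)) {
    e <- fit$estimate
    ta <- if (is.na(e[["T_a"]])) Inf else e[["T_a"]]
    grid <- exp(seq(log(min(object$tau_us)), log(max(object$tau_us)),
                    length.out = 200))
    curve <- tibble::tibble(
      tau_us = grid,
      pl = e[["I_inf"]] + e[["C_a"]] * exp(-grid / ta) +
        e[["C_b"]] * exp(-grid / e[["T_b"]]))
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  p
}

#' Plot a moving-window T1 series
#'
#' Outlier-flagged windows are shown hollow.
#'
#' @param object A `t1_series` (run [iqr_filter()] first to flag outliers).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.t1_series <- function(object, ...) {
  if (!"outlier" %in% names(object)) object$outlier <- FALSE
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$t1_us,
                                       shape = .data$outlier)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = "time (min)", y = "T1 (us)", shape = "outlier")
}

#' Plot a combined normalized reaction timeline
#'
#' The five normalized channels of a pipeline run on one time axis.
#'
#' @param object A `timeline_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.timeline_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_min",
                              names_to = "channel", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$percent,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "normalized signal (%)",
                  colour = "channel")
}

#' Plot a spectrum
#'
#' @param object A `spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrum <- function(object, ...) {
  xlab <- if (attr(object, "abscissa_unit") == "nm") "wavelength (nm)"
  else "Raman shift (cm-1)"
  ggplot2::ggplot(object, ggplot2::aes(.data$abscissa, .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xlab, y = attr(object, "intensity_unit"))
}
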