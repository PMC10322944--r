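# tidy()/glance() and autoplot() methods for the fitted-object classes

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a DAS fit into a long tibble
#'
#' @param x A `das_fit`.
#' @param ... Unused.
#' @return Tibble: `component`, `lifetime`, `wavelength`, `amplitude`.
#' @export
tidy.das_fit <- function(x, ...) {
  k <- length(x$lifetimes)
  wl <- x$surface$wavelengths
  tibble::tibble(
    component = rep(sprintf("tau%d", seq_len(k)), each = length(wl)),
    lifetime = rep(x$lifetimes, each = length(wl)),
    wavelength = rep(wl, times = k),
    amplitude = as.vector(t(x$amplitude_spectra))
  )
}

#' @rdname tidy.das_fit
#' @export
glance.das_fit <- function(x, ...) {
  tibble::tibble(
    n_components = length(x$lifetimes),
    fit_residual_rms = x$fit_residual_rms,
    converged = x$converged,
    n_times = length(x$surface$times),
    n_wavelengths = length(x$surface$wavelengths)
  )
}

#' Tidy an SAS result into a long tibble
#'
#' @param x An `sas_result`.
#' @param ... Unused.
#' @return Tibble: `species`, `wavelength`, `amplitude`.
#' @export
tidy.sas_result <- function(x, ...) {
  wl <- if (!is.null(x$das)) x$das$surface$wavelengths else
    seq_len(ncol(x$species_spectra))
  sp <- x$scheme$compartments
  tibble::tibble(
    species = rep(sp, each = length(wl)),
    wavelength = rep(wl, times = length(sp)),
    amplitude = as.vector(t(x$species_spectra))
  )
}

#' Tidy a target fit
#'
#' @param x A `target_fit`.
#' @param ... Unused.
#' @return Tibble with one row per fitted lifetime: `term`, `lifetime`,
#'   `std_error`, `poorly_determined`.
#' @export
tidy.target_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$lifetimes),
    lifetime = as.numeric(x$lifetimes),
    std_error = as.numeric(x$lifetime_se),
    poorly_determined = as.logical(x$poorly_determined)
  )
}

#' @rdname tidy.target_fit
#' @export
glance.target_fit <- function(x, ...) {
  tibble::tibble(
    n_compartments = length(x$scheme$compartments),
    fit_residual_rms = x$fit_residual_rms,
    converged = x$converged
  )
}

#' Plot decay-associated spectra
#'
#' One line per component, amplitude against wavelength, labelled by the
#' fitted lifetime.
#'
#' @param object A `das_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.das_fit <- function(object, ...) {
  td <- tidy(object)
  td$label <- sprintf("%.3g ps", td$lifetime)
  ggplot2::ggplot(td, ggplot2::aes(.data$wavelength, .data$amplitude,
                                   colour = .data$label)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "amplitude",
                  colour = "lifetime", title = "Decay-associated spectra") +
    ggplot2::theme_minimal()
}

#' Plot species-associated spectra
#'
#' @param object An `sas_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sas_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$wavelength, .data$amplitude,
                               colour = .data$species)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "amplitude",
                  title = "Species-associated spectra") +
    ggplot2::theme_minimal()
}

#' Heatmap of a time-resolved surface
#'
#' @param object A `time_resolved_surface`.
#' @param ... Unused.
#' @return A ggplot (time on a symmetric-log-like axis is left to the
#'   caller; the default axis is linear).
#' @export
autoplot.time_resolved_surface <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$wavelength, .data$time,
                               fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "wavelength (nm)", y = "time (ps)") +
    ggplot2::theme_minimal()
}

#' Bar chart of inter-ring angles per bilin
#'
#' @param conformations Tibble from [bilin_conformation()].
#' @return A ggplot with one panel group per angle.
#' @export
plot_conformation <- function(conformations) {
  long <- tidyr::pivot_longer(
    conformations[, c("label", "theta_ab", "theta_bc", "theta_cd")],
    -"label", names_to = "angle", values_to = "degrees")
  ggplot2::ggplot(long, ggplot2::aes(.data$label, .data$degrees,
                                     fill = .data$angle)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "inter-ring angle (degrees)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom rlang .data
NULL
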