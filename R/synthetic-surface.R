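# Synthetic spectroscopy fixtures: surfaces generated from a kinetic scheme
# and Gaussian spectral bands, with known ground truth attached.

#' Generate a time-resolved surface from a kinetic scheme
#'
#' `signal = concentration_profiles(scheme, times, irf) x B + noise`, where
#' row i of the band matrix `B` is the spectrum of compartment i: a Gaussian
#' band at `band_centers[i]` of standard-deviation width `band_widths[i]`,
#' multiplied by `band_signs[i]`. In TA mode a negative (bleach) band is
#' paired with a positive excited-state-absorption lobe red-shifted by
#' `esa_offset` and scaled by `esa_scale`, so fits face realistic sign
#' structure. Noise is i.i.d. Gaussian with standard deviation
#' `noise_sigma x max(|clean signal|)` under a fixed seed, making the
#' generator a pure function of its arguments.
#'
#' @param scheme A `kinetic_scheme`.
#' @param times,wavelengths Strictly increasing axes (ps, nm). Negative
#'   (pre-excitation) times are allowed and retained.
#' @param band_centers,band_widths Numeric, one per compartment (nm).
#' @param band_signs One sign per compartment; default all `-1` for
#'   `mode = "TA"` (bleach), all `+1` for `mode = "fluorescence"`.
#' @param irf An `irf_model` or `NULL`.
#' @param noise_sigma Noise level as a fraction of the signal maximum.
#' @param seed Integer seed for the noise.
#' @param mode `"TA"` or `"fluorescence"`.
#' @param esa_offset,esa_scale Excited-state-absorption lobe offset (nm) and
#'   relative amplitude (TA mode only).
#' @return A `time_resolved_surface` with attribute `truth`: list of the
#'   generating `scheme`, `bands` matrix, and clean `signal`.
#' @export
make_surface <- function(scheme, times, wavelengths,
                         band_centers, band_widths, band_signs = NULL,
                         irf = NULL, noise_sigma = 0, seed = 1L,
                         mode = c("TA", "fluorescence"),
                         esa_offset = 40, esa_scale = 0.5) {
  mode <- match.arg(mode)
  n <- length(scheme$compartments)
  stopifnot(length(band_centers) == n, noise_sigma >= 0)
  band_widths <- rep_len(band_widths, n)
  if (is.null(band_signs)) {
    band_signs <- rep(if (mode == "TA") -1 else 1, n)
  }
  stopifnot(length(band_signs) == n)
  B <- t(vapply(seq_len(n), function(i) {
    g <- band_signs[i] * gauss_band(wavelengths, band_centers[i], band_widths[i])
    if (mode == "TA" && band_signs[i] < 0) {
      g <- g + esa_scale * gauss_band(wavelengths, band_centers[i] + esa_offset,
                                      band_widths[i] * 1.2)
    }
    g
  }, numeric(length(wavelengths))))
  C <- concentration_profiles(scheme, times, irf)
  clean <- C %*% B
  signal <- clean
  if (noise_sigma > 0) {
    signal <- clean + with_local_seed(seed, {
      matrix(stats::rnorm(length(clean), sd = noise_sigma * max(abs(clean))),
             nrow = nrow(clean))
    })
  }
  out <- time_resolved_surface(times, wavelengths, signal,
                               metadata = list(mode = mode,
                                               noise_sigma = noise_sigma,
                                               seed = seed))
  attr(out, "truth") <- list(scheme = scheme, bands = B, signal = clean)
  out
}

gauss_band <- function(wl, center, width) {
  exp(-((wl - center)^2) / (2 * width^2))
}

#' Preset synthetic surfaces emulating the CpcL-rod experiments
#'
#' `"cpcl_ta"`: transient absorption between 550 and 700 nm under the
#' five-compartment funnel of [scheme_ta_default()] (lifetimes
#' 3.6/25/200/200/1999 ps), bleach bands at 631/637/644/668/669 nm, a
#' 100 fs Gaussian IRF, and a time axis spanning -1 to 6000 ps (linear
#' through the IRF region, logarithmic beyond). `"cpcl_fl"`: time-resolved
#' fluorescence under [scheme_fl_default()] (101/401/401/1999 ps) with
#' emission bands at 645/651/669/672 nm.
#'
#' @param preset `"cpcl_ta"` or `"cpcl_fl"`.
#' @param noise_sigma Noise fraction (default 0.01, i.e. 1 percent of the
#'   signal maximum).
#' @param seed Integer seed.
#' @return A `time_resolved_surface` with ground truth attached.
#' @export
make_surface_preset <- function(preset = c("cpcl_ta", "cpcl_fl"),
                                noise_sigma = 0.01, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "cpcl_ta") {
    make_surface(
      scheme = scheme_ta_default(),
      times = funnel_time_axis(t_min = -1, t_dense = 2, t_max = 6000,
                               n_log = 60, dt_dense = 0.1),
      wavelengths = seq(550, 700, by = 2),
      band_centers = c(631, 637, 644, 668, 669),
      band_widths = c(10, 10, 10, 11, 11),
      irf = irf_model(fwhm = 0.1),
      noise_sigma = noise_sigma, seed = seed, mode = "TA"
    )
  } else {
    make_surface(
      scheme = scheme_fl_default(),
      times = funnel_time_axis(t_min = -20, t_dense = 50, t_max = 8000,
                               n_log = 70, dt_dense = 5),
      wavelengths = seq(600, 720, by = 2),
      band_centers = c(645, 651, 669, 672),
      band_widths = c(9, 9, 10, 10),
      irf = irf_model(fwhm = 8),
      noise_sigma = noise_sigma, seed = seed, mode = "fluorescence"
    )
  }
}

# linear sampling through the IRF region, logarithmic out to t_max
funnel_time_axis <- function(t_min, t_dense, t_max, n_log, dt_dense) {
  dense <- seq(t_min, t_dense, by = dt_dense)
  sparse <- exp(seq(log(t_dense * 1.2), log(t_max), length.out = n_log))
  sort(unique(c(dense, sparse)))
}
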