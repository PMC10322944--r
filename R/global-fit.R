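#' Global multi-exponential fit: decay-associated spectra
#'
#' Fits the surface as `S(t, l) = sum_k A_k(l) e_k(t)` where every
#' wavelength shares the same k IRF-convolved exponential lifetimes and the
#' amplitude spectra `A_k` are free per wavelength. The nonlinear search is
#' over log-lifetimes (positivity by construction) with
#' Levenberg-Marquardt least squares; at each step the amplitudes are solved
#' exactly by linear least squares (variable projection), so only k
#' nonlinear parameters remain. Deterministic given the same data and
#' starting values.
#'
#' @param surface A `time_resolved_surface`.
#' @param n_components Number of exponential components k (>= 1). When k
#'   exceeds the SVD rank estimate a warning is issued, not an error.
#' @param irf An `irf_model` or `NULL` (no convolution; negative times then
#'   contribute zero model signal).
#' @param init_lifetimes `"auto"` (log-spaced between the median time step
#'   and the time span) or a numeric vector of k starting lifetimes, ps.
#' @return Object of class `das_fit`: `lifetimes` (ps, ascending),
#'   `amplitude_spectra` (k x n_wavelengths, rows matching `lifetimes`),
#'   `fit_residual_rms`, `converged`, `lifetime_se` (asymptotic standard
#'   errors, ps), `irf`, `surface`, `info` (optimizer diagnostics).
#' @examples
#' sc <- kinetic_scheme("A", loss = c(A = 1 / 50))
#' surf <- make_surface(sc, times = seq(0, 400, by = 2),
#'                      wavelengths = seq(600, 700, by = 5),
#'                      band_centers = 650, band_widths = 12,
#'                      noise_sigma = 0)
#' fit <- global_fit_das(surf, 1)
#' fit$lifetimes
#' @export
global_fit_das <- function(surface, n_components, irf = NULL,
                           init_lifetimes = "auto") {
  stopifnot(inherits(surface, "time_resolved_surface"),
            n_components >= 1, n_components == round(n_components))
  k <- as.integer(n_components)
  rk <- svd_rank(surface)$rank
  if (k > rk && rk > 0) {
    warning("n_components (", k, ") exceeds the SVD rank estimate (", rk,
            "); the fit may be under-determined", call. = FALSE)
  }
  tt <- surface$times
  if (identical(init_lifetimes, "auto")) {
    span <- max(tt) - (if (is.null(irf)) max(min(tt), 0) else irf$t0)
    dt <- stats::median(diff(tt))
    init_lifetimes <- exp(seq(log(max(dt, span * 1e-4)), log(span), length.out = k))
  }
  stopifnot(length(init_lifetimes) == k, all(init_lifetimes > 0))
  S <- surface$signal
  resid_fun <- function(logtau) {
    pr <- das_projection(S, tt, exp(logtau), irf)
    as.vector(pr$residuals)
  }
  if (k == 0) stop("n_components must be >= 1", call. = FALSE)
  fit <- minpack.lm::nls.lm(
    par = log(init_lifetimes), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  tau <- exp(fit$par)
  pr <- das_projection(S, tt, tau, irf)
  ord <- order(tau)
  # asymptotic SE of tau from the log-lifetime covariance (delta method)
  se <- rep(NA_real_, k)
  cv <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0)) * tau
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("global fit did not converge (", fit$message, ")", call. = FALSE)
  }
  structure(
    list(
      lifetimes = tau[ord],
      amplitude_spectra = pr$amplitudes[ord, , drop = FALSE],
      fit_residual_rms = sqrt(mean(pr$residuals^2)),
      converged = converged,
      lifetime_se = se[ord],
      irf = irf,
      surface = surface,
      info = list(message = fit$message, info = fit$info,
                  niter = fit$niter, deviance = fit$deviance)
    ),
    class = "das_fit"
  )
}

# variable projection: basis of convolved exponentials, amplitudes by OLS
das_projection <- function(S, times, taus, irf) {
  E <- vapply(taus, function(tau) conv_exp(times, 1 / tau, irf),
              numeric(length(times)))
  qr_E <- qr(E)
  A <- qr.coef(qr_E, S)
  A[is.na(A)] <- 0     # rank-deficient basis (duplicate lifetimes)
  list(amplitudes = A, residuals = S - E %*% A, basis = E)
}

#' Model reconstruction from a DAS fit
#'
#' @param das A `das_fit`.
#' @return Matrix of the fitted model surface (times x wavelengths).
#' @export
das_reconstruction <- function(das) {
  E <- vapply(das$lifetimes, function(tau) conv_exp(das$surface$times, 1 / tau, das$irf),
              numeric(length(das$surface$times)))
  E %*% das$amplitude_spectra
}

#' @export
print.das_fit <- function(x, ...) {
  cat("Global multi-exponential fit (", length(x$lifetimes), " components)\n", sep = "")
  cat("  lifetimes (ps):", paste(signif(x$lifetimes, 4), collapse = ", "), "\n")
  cat(sprintf("  residual rms: %.3g; converged: %s\n",
              x$fit_residual_rms, x$converged))
  invisible(x)
}
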