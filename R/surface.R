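#' Time-resolved spectral surface
#'
#' Container for a transient-absorption (delta-A) or time-resolved
#' fluorescence surface: a signal matrix over strictly increasing time (ps)
#' and wavelength (nm) axes, plus free-form metadata (excitation wavelength,
#' detection mode, ...).
#'
#' @param times Strictly increasing numeric vector, ps.
#' @param wavelengths Strictly increasing numeric vector, nm.
#' @param signal Numeric matrix, `length(times) x length(wavelengths)`,
#'   all finite.
#' @param metadata Named list; `mode` conventionally `"TA"` or
#'   `"fluorescence"`.
#' @return Object of class `time_resolved_surface`.
#' @export
time_resolved_surface <- function(times, wavelengths, signal,
                                  metadata = list()) {
  times <- as.numeric(times); wavelengths <- as.numeric(wavelengths)
  signal <- as.matrix(signal)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing", call. = FALSE)
  if (!all(dim(signal) == c(length(times), length(wavelengths)))) {
    stop("signal must be length(times) x length(wavelengths)", call. = FALSE)
  }
  if (!all(is.finite(signal))) stop("signal contains non-finite values", call. = FALSE)
  structure(list(times = times, wavelengths = wavelengths,
                 signal = unname(signal), metadata = metadata),
            class = "time_resolved_surface")
}

#' @export
print.time_resolved_surface <- function(x, ...) {
  cat(sprintf("Time-resolved surface: %d times (%g..%g ps) x %d wavelengths (%g..%g nm)\n",
              length(x$times), min(x$times), max(x$times),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, function(v) paste(format(v), collapse = ","), ""),
                             sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Long-format view of a surface
#'
#' @param x A `time_resolved_surface`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `wavelength`, `signal`.
#' @export
as_tibble.time_resolved_surface <- function(x, ...) {
  tibble::tibble(
    time = rep(x$times, times = length(x$wavelengths)),
    wavelength = rep(x$wavelengths, each = length(x$times)),
    signal = as.vector(x$signal)
  )
}

#' Read / write a surface as delimited text
#'
#' Format: first row holds the wavelength axis (nm) with an empty leading
#' cell, first column holds the time axis (ps), body is the signal. A JSON
#' sidecar `<path>.json`, when present, is read into `metadata` (and written
#' by `write_surface()` when metadata is non-empty).
#'
#' @param path CSV/TSV file path (delimiter inferred from extension; `.tsv`
#'   means tab).
#' @return `read_surface()`: a `time_resolved_surface`; `write_surface()`:
#'   `path`, invisibly.
#' @export
read_surface <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   colClasses = "numeric", skip = 1))
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  wl <- as.numeric(header[-1])
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  time_resolved_surface(m[, 1], wl, m[, -1, drop = FALSE], metadata = meta)
}

#' @rdname read_surface
#' @param surface A `time_resolved_surface`.
#' @export
write_surface <- function(surface, path) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  header <- paste(c("", format(surface$wavelengths, trim = TRUE)), collapse = sep)
  body <- cbind(surface$times, surface$signal)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(body, con, sep = sep, col.names = FALSE, row.names = FALSE)
  if (length(surface$metadata)) {
    jsonlite::write_json(surface$metadata, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Singular-value decomposition rank estimate
#'
#' Singular values of the signal matrix, sorted descending, and the count
#' above a noise floor. The floor is `noise_factor` times the median of the
#' trailing half of the singular-value spectrum — the trailing values sample
#' the noise plateau. An all-zero matrix has rank 0.
#'
#' @param surface A `time_resolved_surface` (or bare matrix).
#' @param noise_factor Multiplier on the trailing-half median (default 5).
#' @return List with `singular_values` and `rank`.
#' @export
svd_rank <- function(surface, noise_factor = 5) {
  m <- if (inherits(surface, "time_resolved_surface")) surface$signal else as.matrix(surface)
  stopifnot(length(m) > 0)
  sv <- svd(m, nu = 0, nv = 0)$d
  if (max(sv) == 0) return(list(singular_values = sv, rank = 0L))
  trailing <- if (length(sv) >= 4) {
    sv[seq.int(ceiling(length(sv) / 2) + 1, length(sv))]
  } else {
    sv[length(sv)]
  }
  # noise plateau estimate, but never below numerical rank resolution
  # (noiseless data plateau at machine precision, not at a noise floor)
  floor_val <- max(noise_factor * stats::median(trailing),
                   max(sv) * 1e-9)
  if (!is.finite(floor_val)) floor_val <- max(sv) * 1e-9
  list(singular_values = sv, rank = as.integer(sum(sv > floor_val)))
}
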