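# Duration filtering, fixed-length resampling, z-normalisation.

#' Filter nanospectra by duration
#'
#' Keeps events whose duration is at least `min_us` microseconds (events
#' *shorter than* the threshold are removed, so the boundary is kept),
#' preserving input order.
#'
#' @param spectra List of blockade events / nanospectra, each with a
#'   `duration_us` field (see [detect_events()] and
#'   [simulate_nanospectrum()]).
#' @param min_us Minimum duration in microseconds (default 170, the
#'   analysis-time filter; extraction uses a separate 42 us floor).
#' @return The filtered list.
#' @export
filter_by_duration <- function(spectra, min_us = 170) {
  if (!is.numeric(min_us) || length(min_us) != 1L || min_us < 0)
    stop("min_us must be a single non-negative number")
  keep <- vapply(spectra, function(s) s$duration_us >= min_us, logical(1L))
  spectra[keep]
}

#' Resample a signal to a fixed length
#'
#' Produces a length-`m` version of a signal: when the input is longer than
#' `m` neighbouring points are averaged (bin `j` covers input indices
#' `[round(jL/m), round((j+1)L/m))`, 0-based, round-half-up), when shorter
#' the signal is linearly interpolated at `m` equally spaced positions
#' spanning the input support, and when equal it is returned unchanged.
#'
#' @param x Numeric signal vector (length `L >= 2`), or a nanospectrum
#'   object whose `signal` field is used.
#' @param m Target length (default 500).
#' @return Numeric vector of length `m`.
#' @export
#' @examples
#' resample_spectrum(1:10, 5)
resample_spectrum <- function(x, m = 500L) {
  if (is.list(x)) x <- x$signal
  if (!is.numeric(x)) stop("x must be numeric")
  L <- length(x)
  if (L < 2L) stop("too short to resample")
  m <- as.integer(m)
  if (m < 1L) stop("m must be positive")
  if (L == m) return(as.numeric(x))
  if (L > m) {
    # round-half-up boundaries give equal-as-possible bins
    bounds <- floor((0:m) * L / m + 0.5)
    grp <- rep.int(seq_len(m), diff(bounds))
    as.numeric(tapply(x, grp, mean))
  } else {
    approx(x = seq_len(L), y = x, xout = seq(1, L, length.out = m))$y
  }
}

#' Z-normalise a signal
#'
#' Centres and scales to zero mean and unit variance using the population
#' standard deviation, so the output SD is exactly 1. Affine-invariant:
#' `znormalize(a * x + b)` equals `znormalize(x)` for `a > 0`.
#'
#' @param x Numeric vector with positive variance.
#' @return Numeric vector with mean 0 and population SD 1.
#' @export
znormalize <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) stop("x must be numeric, length >= 2")
  if (any(!is.finite(x))) stop("non-finite values")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop("zero variance")
  (x - mu) / s
}

is_znormalized <- function(x, tol = 1e-6) {
  abs(mean(x)) < tol && abs(sqrt(mean((x - mean(x))^2)) - 1) < tol
}

#' Resample and normalise a set of events into a spectrum matrix
#'
#' Convenience wrapper: applies [resample_spectrum()] and [znormalize()] to
#' each event and stacks the results.
#'
#' @param spectra List of events/nanospectra.
#' @param m Resample length (default 500).
#' @param normalize Z-normalise each row (default `TRUE`).
#' @return Numeric matrix, one row per spectrum, `m` columns.
#' @export
resample_matrix <- function(spectra, m = 500L, normalize = TRUE) {
  rows <- lapply(spectra, function(s) {
    v <- resample_spectrum(s, m)
    if (normalize) v <- znormalize(v)
    v
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- matrix(numeric(0), 0L, m)
  out
}
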