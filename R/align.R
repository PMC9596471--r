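# Slope-constrained DTW wrapper, Pearson correlation, and the path audit.

#' Pearson correlation coefficient
#'
#' Standard Pearson correlation with explicit degenerate-input errors.
#'
#' @param x,y Numeric vectors of equal length (at least 2), neither
#'   constant.
#' @return Correlation in `[-1, 1]`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 points")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: constant input")
  cor(x, y)
}

#' Slope-constrained dynamic time warping
#'
#' Aligns two equal-length z-normalised spectra with a DTW whose step
#' blocks are (1,1), (2,3) and (3,2), restricting every locally matched
#' time-period ratio to `[2/3, 3/2]` (so any 6 points on one axis consume
#' between 4 and 9 on the other, and singularities are impossible). Local
#' cost is the squared error; the dynamic program fills an
#' `(m+1) x (m+1)` table in `O(m^2)`. Traceback tie-breaks prefer (1,1),
#' then (2,3), then (3,2), so results are deterministic.
#'
#' @param S,T Numeric vectors of equal length `m >= 3`, z-normalised
#'   (checked at tolerance 1e-6; see [znormalize()]).
#' @return Object of class `dtw_alignment`: list with `distance` (total
#'   squared error along the optimal path), `path` (two-column matrix of
#'   1-based index pairs from (1,1) to (m,m)), `pcc` (Pearson correlation
#'   of S and T read along the path) and `m`.
#' @export
#' @examples
#' s <- znormalize(sin(seq(0, 4 * pi, length.out = 50)))
#' a <- constrained_dtw(s, s)
#' a$distance
constrained_dtw <- function(S, T) {
  if (length(S) != length(T)) stop("length mismatch")
  if (!is_znormalized(S) || !is_znormalized(T))
    stop("inputs must be z-normalized (zero mean, unit variance)")
  res <- dtw_core(as.numeric(S), as.numeric(T))
  path <- res$path
  structure(list(distance = res$distance,
                 path = path,
                 pcc = pcc(S[path[, 1L]], T[path[, 2L]]),
                 m = length(S)),
            class = "dtw_alignment")
}

#' Pearson correlation along a warp path
#'
#' Reads `S` and `T` along the path pairs (each pair contributing once,
#' duplicated indices allowed) and correlates the two resulting sequences.
#'
#' @param S,T The aligned spectra.
#' @param path Two-column index matrix as returned in a `dtw_alignment`.
#' @return Correlation in `[-1, 1]`.
#' @export
pcc_on_path <- function(S, T, path) {
  if (inherits(path, "dtw_alignment")) path <- path$path
  if (max(path[, 1L]) > length(S) || max(path[, 2L]) > length(T))
    stop("path indices exceed spectrum length")
  pcc(S[path[, 1L]], T[path[, 2L]])
}

#' Audit the slope constraint of a warp path
#'
#' Checks that every window of a traceback matching 6 points on the
#' theoretical axis consumes between 4 and 9 points on the empirical axis
#' (and symmetrically), the direct consequence of the 2/3..3/2 slope
#' bound.
#'
#' @param path Two-column index matrix or `dtw_alignment`.
#' @param window Window size on the reference axis (default 6).
#' @param lo,hi Allowed consumed-point range (default 4 and 9).
#' @return `TRUE` invisibly if the path passes; otherwise an error.
#' @export
audit_path_slope <- function(path, window = 6L, lo = 4L, hi = 9L) {
  if (inherits(path, "dtw_alignment")) path <- path$path
  check_axis <- function(a, b) {
    # for each window of `window` consecutive values of a, count distinct b
    m <- max(a)
    if (m < window) return(invisible(TRUE))
    # first and last path row touching each a index
    first <- tapply(b, a, min)
    last <- tapply(b, a, max)
    for (s in seq_len(m - window + 1L)) {
      consumed <- last[[s + window - 1L]] - first[[s]] + 1L
      if (consumed < lo || consumed > hi)
        stop(sprintf(
          "slope violation: %d points [%d..%d] matched against %d points",
          window, s, s + window - 1L, consumed))
    }
    invisible(TRUE)
  }
  check_axis(path[, 2L], path[, 1L])
  check_axis(path[, 1L], path[, 2L])
  invisible(TRUE)
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("dtw_alignment: m = %d, distance = %.6g, path PCC = %.4f\n",
              x$m, x$distance, x$pcc))
  invisible(x)
}

#' @export
#' @method plot dtw_alignment
plot.dtw_alignment <- function(x, ...) {
  plot(x$path[, 2L], x$path[, 1L], type = "s",
       xlab = "theoretical index", ylab = "empirical index", ...)
  abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}
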