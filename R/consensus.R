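# Orientation, average consensus, and the progressive-alignment consensus.

#' Decide the orientation of a nanospectrum
#'
#' A forward nanospectrum enters the pore N-terminus first. The call
#' compares the plain (un-warped) Pearson correlation of the spectrum and
#' of its reversal against the theoretical template: forward iff
#' `PCC(S, T) > PCC(rev(S), T)`, otherwise backward (ties are backward,
#' with an ambiguity flag, since many real spectra separate the two PCCs
#' only slightly).
#'
#' @param S Resampled empirical spectrum (length m, non-constant).
#' @param template Theoretical template: a `theoretical_spectrum` or its
#'   expanded length-m vector (conventionally from the 1AAV model).
#' @return List with `orientation` (`"forward"`/`"backward"`),
#'   `pcc_forward`, `pcc_backward`, `ambiguous` (logical), `margin`.
#' @export
assign_orientation <- function(S, template) {
  te <- if (inherits(template, "theoretical_spectrum")) template$expanded
        else template
  pf <- pcc(S, te)
  pb <- pcc(rev(S), te)
  list(orientation = if (pf > pb) "forward" else "backward",
       pcc_forward = pf, pcc_backward = pb,
       ambiguous = pf == pb, margin = pf - pb)
}

#' Orient a spectrum matrix against a template
#'
#' Applies [assign_orientation()] to every row and flips the backward rows
#' so all spectra share the forward orientation.
#'
#' @param mat Spectrum matrix (rows = resampled spectra).
#' @param template Theoretical template (see [assign_orientation()]).
#' @return List with `matrix` (oriented), `orientation` (character
#'   vector), `n_forward`, `n_backward`, `n_ambiguous`.
#' @export
orient_spectra <- function(mat, template) {
  calls <- apply(mat, 1L, assign_orientation, template = template,
                 simplify = FALSE)
  ori <- vapply(calls, `[[`, character(1L), "orientation")
  out <- mat
  back <- which(ori == "backward")
  if (length(back)) out[back, ] <- out[back, ncol(mat):1L, drop = FALSE]
  list(matrix = out, orientation = ori,
       n_forward = sum(ori == "forward"),
       n_backward = sum(ori == "backward"),
       n_ambiguous = sum(vapply(calls, `[[`, logical(1L), "ambiguous")))
}

#' Average consensus nanospectrum
#'
#' Element-wise arithmetic mean of oriented, resampled nanospectra.
#'
#' @param mat Spectrum matrix (>= 1 row, all rows oriented, length m).
#' @return Object of class `consensus_spectrum`: list with `values`
#'   (length m), `weight`, `n_contributing`, `kind = "average"`.
#' @export
average_consensus <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  if (nrow(mat) < 1L) stop("need at least one spectrum")
  if (any(!is.finite(mat))) stop("non-finite values in spectra")
  structure(list(values = colMeans(mat), weight = 1,
                 n_contributing = nrow(mat), kind = "average"),
            class = "consensus_spectrum")
}

#' Rank spectra by DTW distance to a consensus
#'
#' Ascending by slope-constrained DTW distance between each z-normalised
#' spectrum and the z-normalised consensus; ties keep input order.
#'
#' @param mat Spectrum matrix.
#' @param consensus A `consensus_spectrum` or numeric vector.
#' @return List with `order` (row indices, best first) and `distance`
#'   (in input order).
#' @export
rank_by_alignment <- function(mat, consensus) {
  if (is.null(dim(mat)) || nrow(mat) == 0L)
    return(list(order = integer(0L), distance = numeric(0L)))
  cv <- znormalize(consensus_values(consensus))
  d <- apply(mat, 1L, function(row)
    constrained_dtw(znormalize(row), cv)$distance)
  list(order = order(d), distance = d)
}

consensus_values <- function(x) {
  if (inherits(x, "consensus_spectrum")) x$values else as.numeric(x)
}

#' Progressive-alignment consensus nanospectrum
#'
#' Refines an average consensus with its top-ranked spectra: the spectra
#' are ranked once by DTW distance to the average consensus, then for
#' `i = 1..t` the i-th best spectrum is aligned to the current consensus,
#' projected onto the consensus axis (for each consensus index, the mean
#' of the spectrum values the warp path matches to it) and folded in as a
#' weighted average with weight `u + i - 1` for the consensus and 1 for
#' the spectrum.
#'
#' @param mat Spectrum matrix (oriented).
#' @param consensus Average consensus (default computed from `mat`).
#' @param t Number of top-ranked spectra to fold in (default 50; capped at
#'   the available count, with a warning).
#' @param u Initial consensus weight (default 30).
#' @return Object of class `consensus_spectrum` with `kind = "alignment"`
#'   and `weight = u + t`.
#' @export
progressive_consensus <- function(mat, consensus = average_consensus(mat),
                                  t = 50L, u = 30) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  t <- as.integer(t)
  if (t > nrow(mat)) {
    warning(sprintf("only %d spectra available; using all", nrow(mat)))
    t <- nrow(mat)
  }
  rk <- rank_by_alignment(mat, consensus)
  C <- consensus_values(consensus)
  for (i in seq_len(t)) {
    spec <- mat[rk$order[i], ]
    al <- constrained_dtw(znormalize(spec), znormalize(C))
    proj <- project_on_consensus(spec, al$path, length(C))
    C <- ((u + i - 1) * C + proj) / (u + i)
  }
  structure(list(values = C, weight = u + t,
                 n_contributing = nrow(mat), kind = "alignment"),
            class = "consensus_spectrum")
}

project_on_consensus <- function(spec, path, m) {
  # mean of the spectrum values matched to each consensus index j
  sums <- tabulate_sum(path[, 2L], spec[path[, 1L]], m)
  counts <- tabulate(path[, 2L], m)
  if (any(counts == 0L)) stop("uncovered consensus index")  # impossible: path complete
  sums / counts
}

tabulate_sum <- function(bin, w, nbins) {
  as.numeric(rowsum(w, factor(bin, levels = seq_len(nbins))))
}

#' @export
print.consensus_spectrum <- function(x, ...) {
  cat(sprintf("consensus_spectrum (%s): %d points from %d spectra, weight %g\n",
              x$kind, length(x$values), x$n_contributing, x$weight))
  invisible(x)
}

#' @export
#' @method plot consensus_spectrum
plot.consensus_spectrum <- function(x, template = NULL, ...) {
  v <- znormalize(x$values)
  plot(seq_along(v) / length(v), v, type = "l", col = "darkorange",
       xlab = "normalized duration", ylab = "blockade (z-score)", ...)
  if (!is.null(template)) {
    te <- if (inherits(template, "theoretical_spectrum")) template$expanded
          else template
    lines(seq_along(te) / length(te), znormalize(te), col = "blue")
    legend("topright", legend = c("consensus", "theoretical"),
           col = c("darkorange", "blue"), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Extract per-residue data points from an alignment
#'
#' Given a warp path aligning a consensus (empirical axis) with a
#' theoretical spectrum (theoretical axis), returns for each residue the
#' mean of the consensus values matched to the theoretical indices in that
#' residue's dwell segment `[(k-1) m/n, k m/n)`. Yields exactly `n`
#' observed values, one per residue.
#'
#' @param consensus Consensus values (length m, same scale as used in the
#'   alignment, typically z-normalised).
#' @param theoretical A `theoretical_spectrum` (provides `n` and `m`).
#' @param path Warp path or `dtw_alignment` from aligning
#'   `znormalize(consensus)` (S side) with the z-normalised expanded
#'   theoretical spectrum (T side).
#' @return Numeric vector of length `n`.
#' @export
extract_residue_datapoints <- function(consensus, theoretical, path) {
  if (inherits(path, "dtw_alignment")) path <- path$path
  cv <- consensus_values(consensus)
  n <- length(theoretical$per_residue)
  m <- theoretical$m
  residue_of <- pmin(floor((path[, 2L] - 1L) * n / m) + 1L, n)
  sums <- tabulate_sum(residue_of, cv[path[, 1L]], n)
  counts <- tabulate(residue_of, n)
  if (any(counts == 0L))
    stop(sprintf("uncovered residue %s", which(counts == 0L)[1L]))
  sums / counts
}
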