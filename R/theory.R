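# Theoretical nanospectra: per-residue model predictions expanded to the
# resample length by linear interpolation between anchors placed at the
# centre of each residue's equal dwell segment.

#' Expand per-residue values to a length-m spectrum
#'
#' Places anchor `k` of `n` at fractional output position `(k - 0.5) * m/n`
#' (the centre of residue `k`'s equal dwell segment), evaluates a
#' piecewise-linear interpolant through the anchors at the output grid
#' centres `j - 0.5`, and extends flat before the first and after the last
#' anchor.
#'
#' @param per_residue Numeric vector of `n >= 1` per-residue values.
#' @param m Output length (default 500), must be at least `n`.
#' @return Numeric vector of length `m`.
#' @export
#' @examples
#' expand_to_spectrum(c(0, 1), 4)
expand_to_spectrum <- function(per_residue, m = 500L) {
  n <- length(per_residue)
  if (n < 1L) stop("need at least one residue value")
  m <- as.integer(m)
  if (m < n) stop("cannot expand below one point per residue")
  if (n == 1L) return(rep(as.numeric(per_residue), m))
  anchors <- (seq_len(n) - 0.5) * m / n
  approx(x = anchors, y = per_residue, xout = seq_len(m) - 0.5, rule = 2)$y
}

#' Theoretical nanospectrum of a peptide
#'
#' Predicts per-residue blockade signals with a [blockade_model()] and
#' expands them to the resample length with [expand_to_spectrum()].
#'
#' @param peptide Peptide string.
#' @param model A `blockade_model` (default [volume_model()], blockade
#'   proportional to residue volume).
#' @param table Volume table.
#' @param m Expanded length (default 500).
#' @return Object of class `theoretical_spectrum`: list with `peptide`,
#'   `method`, `per_residue` (length n), `expanded` (length m, raw scale)
#'   and `m`. Use [znormalize()] on `expanded` before alignment.
#' @export
#' @examples
#' th <- theoretical_spectrum(peptide_ab42())
#' length(th$expanded)
theoretical_spectrum <- function(peptide, model = volume_model(),
                                 table = load_volume_table(), m = 500L) {
  per_res <- predict(model, peptide, table)
  structure(list(peptide = peptide,
                 method = model$method,
                 per_residue = per_res,
                 expanded = expand_to_spectrum(per_res, m),
                 m = as.integer(m)),
            class = "theoretical_spectrum")
}

#' @export
print.theoretical_spectrum <- function(x, ...) {
  cat(sprintf("theoretical_spectrum (%s): %d residues -> %d points\n",
              x$method, length(x$per_residue), x$m))
  invisible(x)
}

#' @export
#' @method plot theoretical_spectrum
plot.theoretical_spectrum <- function(x, ...) {
  plot(seq_len(x$m) / x$m, znormalize(x$expanded), type = "l", col = "blue",
       xlab = "normalized duration", ylab = "blockade (z-score)", ...)
  invisible(x)
}
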