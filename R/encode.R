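# Residue feature encodings.  Writing the peptide as a1..an with volumes
# b1..bn (virtual flanks b0 = b_{n+1} = 0):
#   1AAV : [b_i]
#   3AAV : [b_i, b_{i-1} + b_{i+1}]
#   AAG  : [x_M, x_S, x_I, x_L], one-hot volume by group (exactly one of the
#          four equals b_i, the rest are 0)
# "-P" variants append x_P, the 1..5 distance-to-terminus feature.

ENCODING_METHODS <- c("1AAV", "3AAV", "AAG", "1AAV-P", "3AAV-P", "AAG-P")

match_encoding <- function(method) {
  m <- toupper(gsub("_", "-", method))
  if (!m %in% ENCODING_METHODS)
    stop(sprintf("unknown encoding method '%s' (one of %s)", method,
                 paste(ENCODING_METHODS, collapse = ", ")))
  m
}

#' Terminal-distance position feature
#'
#' Distance of position `i` from the nearer terminus of an `n`-residue
#' peptide, capped at 5: residues more than 4 positions from both termini
#' count as middle residues and score 5. Computed as `min(i, n - i + 1, 5)`,
#' which is symmetric under sequence reversal.
#'
#' @param i 1-based residue position (vectorised).
#' @param n Peptide length.
#' @return Integer vector of values in 1..5.
#' @export
#' @examples
#' position_feature(1:10, 10)
position_feature <- function(i, n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a single positive integer")
  if (any(!is.finite(i)) || any(i < 1L) || any(i > n))
    stop("position i out of range 1..n")
  pmin(as.integer(i), as.integer(n - i + 1), 5L)
}

#' Encode a peptide as a residue feature matrix
#'
#' Builds the per-residue design matrix for one of the six encodings:
#' single amino-acid volume (`1AAV`), volume plus summed neighbour volumes
#' (`3AAV`), the four volume-group features (`AAG`), and their `-P` variants
#' with an appended terminal-distance position feature.
#'
#' @param peptide Peptide string.
#' @param method Encoding name (`"1AAV"`, `"3AAV"`, `"AAG"`, `"1AAV-P"`,
#'   `"3AAV-P"`, `"AAG-P"`; case-insensitive).
#' @param table A `volume_table`, see [load_volume_table()].
#' @return Numeric matrix with one row per residue; columns depend on the
#'   method (1, 2, 4, 2, 3 or 5 columns). Attribute `method` records the
#'   normalised method name.
#' @export
#' @examples
#' encode_peptide("GAV", "3AAV")
encode_peptide <- function(peptide, method = "1AAV",
                           table = load_volume_table()) {
  method <- match_encoding(method)
  res <- peptide_residues(peptide)
  n <- length(res)
  b <- unname(table[res, "volume_A3"])

  base <- sub("-P$", "", method)
  if (base == "1AAV") {
    X <- cbind(volume = b)
  } else if (base == "3AAV") {
    bp <- c(0, b, 0)                       # b0..b_{n+1}
    flank <- bp[seq_len(n)] + bp[seq_len(n) + 2L]
    X <- cbind(volume = b, flank_volume = flank)
  } else {                                 # AAG
    g <- AA_GROUPS[res]
    X <- sapply(GROUP_LEVELS, function(lev) ifelse(g == lev, b, 0))
    X <- matrix(X, nrow = n,
                dimnames = list(NULL, c("x_M", "x_S", "x_I", "x_L")))
  }
  if (grepl("-P$", method))
    X <- cbind(X, x_P = position_feature(seq_len(n), n))
  attr(X, "method") <- method
  X
}

#' Number of feature columns of an encoding
#' @param method Encoding name.
#' @return Integer column count (1, 2, 4, 2, 3 or 5).
#' @export
encoding_ncol <- function(method) {
  method <- match_encoding(method)
  base <- c(`1AAV` = 1L, `3AAV` = 2L, AAG = 4L)[[sub("-P$", "", method)]]
  base + as.integer(grepl("-P$", method))
}
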