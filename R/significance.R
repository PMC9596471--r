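# Decoy-based empirical significance of a consensus-peptide match.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate random decoy peptides
#'
#' Decoy residues are drawn i.i.d. uniformly from the 20-letter alphabet;
#' reproducible under a seed. Uniform composition is the simplest null and
#' is recorded in the result.
#'
#' @param n Number of decoys (default 10000).
#' @param length Residues per decoy (default 42).
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return Object of class `decoy_set`: character vector of peptides with
#'   attributes `length`, `seed`, `composition = "uniform"`.
#' @export
#' @examples
#' generate_decoys(3, 10, seed = 1)
generate_decoys <- function(n = 10000L, length = 42L, seed = NULL) {
  if (n < 1L || length < 1L) stop("n and length must be positive")
  peps <- with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""),
    character(1L)))
  structure(peps, length = as.integer(length), seed = seed,
            composition = "uniform", class = "decoy_set")
}

#' Decoy PCC distribution
#'
#' Scores each decoy against a consensus nanospectrum: predict per-residue
#' signals with the scoring model, expand, z-normalise, align to the
#' consensus with slope-constrained DTW and record the path PCC. Decoys
#' whose theoretical spectrum is degenerate (constant, e.g. a homopolymer
#' under a position-free model) score a sentinel PCC of -1; they are
#' counted in the returned vector but flagged in attribute `degenerate`
#' and excluded from mean summaries downstream.
#'
#' @param consensus Consensus values (vector or `consensus_spectrum`).
#' @param model Scoring `blockade_model` (conventionally 1AAV-P).
#' @param decoys A `decoy_set` or character vector of peptides.
#' @param table Volume table.
#' @param m Expanded length (default: consensus length).
#' @return Numeric vector of PCCs (one per decoy), attribute `degenerate`
#'   giving indices of sentinel scores.
#' @export
decoy_distribution <- function(consensus, model, decoys,
                               table = load_volume_table(), m = NULL) {
  cv <- znormalize(consensus_values(consensus))
  if (is.null(m)) m <- length(cv)
  pccs <- numeric(length(decoys))
  degen <- integer(0L)
  for (i in seq_along(decoys)) {
    th <- theoretical_spectrum(decoys[[i]], model, table, m)
    te <- tryCatch(znormalize(th$expanded), error = function(e) NULL)
    if (is.null(te)) {
      pccs[i] <- -1
      degen <- c(degen, i)
      next
    }
    pccs[i] <- constrained_dtw(cv, te)$pcc
  }
  attr(pccs, "degenerate") <- degen
  pccs
}

#' Empirical p-value against a decoy distribution
#'
#' The plain counting fraction: the number of decoy PCCs at least as large
#' as the observed PCC, divided by the decoy count. With
#' `add_one = TRUE` the (k+1)/(n+1) variant is returned for users who need
#' a strictly positive p.
#'
#' @param observed Observed PCC of the target match.
#' @param decoy_pccs Numeric vector of decoy PCCs (non-empty).
#' @param add_one Use the (k+1)/(n+1) estimator (default `FALSE`).
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' empirical_p(0.9, c(0.5, 0.95, 0.7, 0.8))
empirical_p <- function(observed, decoy_pccs, add_one = FALSE) {
  if (length(decoy_pccs) == 0L) stop("decoy_pccs must be non-empty")
  k <- sum(decoy_pccs >= observed)
  if (add_one) (k + 1) / (length(decoy_pccs) + 1)
  else k / length(decoy_pccs)
}

#' Significance of a consensus-peptide match
#'
#' Full decoy test: scores the target peptide and `n_decoys` random
#' peptides of the same length against the consensus and reports the
#' empirical p-value of the observed path PCC.
#'
#' @param consensus Consensus values or `consensus_spectrum`.
#' @param peptide Target peptide string.
#' @param model Scoring `blockade_model` (conventionally 1AAV-P).
#' @param n_decoys Decoy count (default 10000).
#' @param seed RNG seed for the decoys.
#' @param table Volume table.
#' @param add_one See [empirical_p()].
#' @return Object of class `nanospec_significance`: list with
#'   `observed_pcc`, `p_value`, `decoy_pccs`, `decoy_mean`, `decoy_sd`
#'   (degenerate sentinels excluded from mean/sd), `n_decoys`,
#'   `n_degenerate`, `seed`.
#' @export
significance_test <- function(consensus, peptide, model,
                              n_decoys = 10000L, seed = NULL,
                              table = load_volume_table(),
                              add_one = FALSE) {
  cv <- znormalize(consensus_values(consensus))
  th <- theoretical_spectrum(peptide, model, table, length(cv))
  observed <- constrained_dtw(cv, znormalize(th$expanded))$pcc
  decoys <- generate_decoys(n_decoys, nchar(peptide), seed)
  dp <- decoy_distribution(cv, model, decoys, table)
  ok <- setdiff(seq_along(dp), attr(dp, "degenerate"))
  structure(list(observed_pcc = observed,
                 p_value = empirical_p(observed, dp, add_one),
                 decoy_pccs = as.numeric(dp),
                 decoy_mean = mean(dp[ok]),
                 decoy_sd = sd(dp[ok]),
                 n_decoys = length(dp),
                 n_degenerate = length(attr(dp, "degenerate")),
                 seed = seed, composition = "uniform"),
            class = "nanospec_significance")
}

#' @export
print.nanospec_significance <- function(x, ...) {
  cat(sprintf(
    "nanospectral match: observed PCC %.4f vs %d decoys (mean %.4f, sd %.4f)\n",
    x$observed_pcc, x$n_decoys, x$decoy_mean, x$decoy_sd))
  cat(sprintf("empirical p-value: %.4g\n", x$p_value))
  if (x$n_degenerate)
    cat(sprintf("(%d degenerate decoys scored as sentinel -1)\n",
                x$n_degenerate))
  invisible(x)
}
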