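# Independent oracles and small fixture builders used across the suite.

# Exhaustive enumeration of all slope-constrained block paths (no
# memoisation): independent of the dynamic-programming implementation.
brute_dtw <- function(S, T) {
  m <- length(S)
  d <- function(i, j) (S[i] - T[j])^2
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- Inf
    if (i >= 1 && j >= 1)
      best <- min(best, rec(i - 1, j - 1) + d(i, j))
    if (i >= 2 && j >= 3)
      best <- min(best, rec(i - 2, j - 3) + d(i - 1, j - 2) + d(i, j - 1) + d(i, j))
    if (i >= 3 && j >= 2)
      best <- min(best, rec(i - 3, j - 2) + d(i - 2, j - 1) + d(i - 1, j) + d(i, j))
    best
  }
  rec(m, m)
}

# Population z-score, written independently of znormalize()
zscore_oracle <- function(x) {
  (x - mean(x)) / sqrt(sum((x - mean(x))^2) / length(x))
}

# Noise-free, equal-dwell simulation whose resampled spectra reproduce the
# expanded theoretical spectrum exactly (duration = m samples).
noiseless_config <- function(n_spectra = 20L, seed = 5L,
                             peptide = peptide_ab42(), m = 500L,
                             sampling_rate = 5e5, p_backward = 0.5) {
  simulation_config(peptide = peptide, n_spectra = n_spectra,
                    noise_sd = 0, dwell_cv = 0,
                    duration_meanlog = log(m / sampling_rate * 1e6),
                    duration_sdlog = 0, p_backward = p_backward,
                    sampling_rate = sampling_rate, seed = seed)
}

noisy_config <- function(n_spectra, noise_sd = 0.3, dwell_cv = 0.3,
                         seed = 1L, peptide = peptide_ab42(), ...) {
  simulation_config(peptide = peptide, n_spectra = n_spectra,
                    noise_sd = noise_sd, dwell_cv = dwell_cv,
                    seed = seed, ...)
}

random_znorm <- function(m) znormalize(rnorm(m))
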