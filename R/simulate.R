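# Synthetic nanospectrum and trace generator with known ground truth.
#
# The generating waveform of one translocation is the piecewise-linear
# interpolant through per-residue anchor signals (the z-scored model
# predictions) placed at the centres of the residues' dwell segments;
# per-residue dwell times carry multiplicative log-normal jitter, residue
# order is reversed for backward translocations, and i.i.d. Gaussian noise
# (in z-units) is added per sample.

#' Simulation configuration
#'
#' Bundles the generating law and nuisance parameters of the synthetic
#' nanospectrum generator. Defaults emulate the reference study's
#' acquisition: 500 kS/s sampling, log-normal blockade durations with
#' median 170 us spanning tens of microseconds to milliseconds, and an
#' even chance of either translocation orientation. Noise and dwell-jitter
#' magnitudes are not printed quantities of any study; the defaults
#' (noise_sd 0.3 z-units, dwell CV 0.3) are moderate values documented in
#' the package vignette.
#'
#' @param peptide Peptide string (default [peptide_ab42()]).
#' @param model Generating `blockade_model` (default [volume_model()]).
#' @param n_spectra Number of events (default 500).
#' @param noise_sd Additive Gaussian noise SD in z-units (default 0.3).
#' @param dwell_cv Coefficient of variation of per-residue dwell times
#'   (default 0.3; 0 = equal dwell).
#' @param duration_meanlog,duration_sdlog Log-normal duration parameters,
#'   microseconds (defaults `log(170)` and 1; `sdlog = 0` gives a fixed
#'   duration).
#' @param p_backward Probability of C-terminus-first translocation
#'   (default 0.5).
#' @param open_current_pA Open-pore current I0 (default 200).
#' @param blockade_mean_pA,blockade_sd_pA Affine map from z-units to pA
#'   (defaults 60 and 10).
#' @param sampling_rate Samples per second (default 5e5).
#' @param seed Base seed; spectrum `i` uses an independent substream
#'   derived from `(seed, i)` so any one spectrum is reproducible in
#'   isolation and nearby base seeds do not share substreams.
#' @param heavy_tail Add a 5% slip-stick mixture of 10x longer durations
#'   (default `FALSE`).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(peptide = peptide_ab42(),
                              model = volume_model(),
                              n_spectra = 500L,
                              noise_sd = 0.3,
                              dwell_cv = 0.3,
                              duration_meanlog = log(170),
                              duration_sdlog = 1,
                              p_backward = 0.5,
                              open_current_pA = 200,
                              blockade_mean_pA = 60,
                              blockade_sd_pA = 10,
                              sampling_rate = 5e5,
                              seed = 1L,
                              heavy_tail = FALSE) {
  stopifnot(noise_sd >= 0, dwell_cv >= 0,
            p_backward >= 0, p_backward <= 1,
            open_current_pA > 0, sampling_rate > 0)
  peptide_residues(peptide)
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: %d spectra of %d-residue peptide (%s model)\n",
    x$n_spectra, nchar(x$peptide), x$model$method))
  cat(sprintf("  noise_sd %.3g, dwell_cv %.3g, p_backward %.2f, seed %d\n",
              x$noise_sd, x$dwell_cv, x$p_backward, x$seed))
  invisible(x)
}

sim_anchor_values <- function(config) {
  znormalize(predict(config$model, config$peptide))
}

# substream seed for spectrum `index`: a multiplicative mix keeps nearby
# base seeds from sharing substreams (all arithmetic below 2^31 - 1)
mix_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

draw_duration_us <- function(config) {
  d <- rlnorm(1L, config$duration_meanlog, config$duration_sdlog)
  if (config$heavy_tail && runif(1L) < 0.05) d <- d * 10
  d
}

#' Simulate one nanospectrum
#'
#' Draws orientation, duration and per-residue dwell times, evaluates the
#' generating waveform at the sample instants, adds noise, and returns the
#' event in measurement units together with its ground truth.
#'
#' @param config A `simulation_config`.
#' @param index Spectrum index, selecting the substream.
#' @return List with `spectrum` (a `blockade_event`) and `truth` (list:
#'   `orientation`, `duration_us`, `dwell_bounds_us` — the cumulative
#'   per-residue dwell boundaries partitioning the duration, in
#'   translocation order — and `anchor_values`, the generating per-residue
#'   z-scored signals in peptide order).
#' @export
simulate_nanospectrum <- function(config, index = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  zfwd <- sim_anchor_values(config)
  n <- length(zfwd)
  with_seed(mix_seed(config$seed, index), {
    backward <- runif(1L) < config$p_backward
    z <- if (backward) rev(zfwd) else zfwd

    if (config$dwell_cv > 0) {
      sdl <- sqrt(log(1 + config$dwell_cv^2))
      d <- rlnorm(n, -sdl^2 / 2, sdl)
    } else d <- rep(1, n)
    d <- d / sum(d)

    dur_us <- draw_duration_us(config)
    L <- as.integer(round(dur_us * 1e-6 * config$sampling_rate))
    tries <- 0L
    while (L < 2L && tries < 100L) {
      dur_us <- draw_duration_us(config)
      L <- as.integer(round(dur_us * 1e-6 * config$sampling_rate))
      tries <- tries + 1L
    }
    if (L < 2L) stop("duration too short for 2 samples after retries")

    anchors <- cumsum(d) - d / 2
    f <- (seq_len(L) - 0.5) / L
    w <- approx(anchors, z, xout = f, rule = 2)$y
    if (config$noise_sd > 0) w <- w + rnorm(L, 0, config$noise_sd)
    signal_pA <- config$blockade_mean_pA + config$blockade_sd_pA * w

    spectrum <- blockade_event(signal = signal_pA, start_time = 0,
                               open_current = config$open_current_pA,
                               sampling_rate = config$sampling_rate)
    list(spectrum = spectrum,
         truth = list(orientation = if (backward) "backward" else "forward",
                      duration_us = L / config$sampling_rate * 1e6,
                      dwell_bounds_us = cumsum(d) * L /
                        config$sampling_rate * 1e6,
                      anchor_values = zfwd))
  })
}

#' Simulate a full nanospectrum dataset
#'
#' @param config A `simulation_config`.
#' @return List with `spectra` (list of `blockade_event`s) and `truth`
#'   (data frame: `index`, `orientation`, `duration_us`, `n_samples`).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(n_spectra = 5, seed = 7))
#' sim$truth
simulate_dataset <- function(config) {
  out <- lapply(seq_len(config$n_spectra), simulate_nanospectrum,
                config = config)
  spectra <- lapply(out, `[[`, "spectrum")
  truth <- data.frame(
    index = seq_along(out),
    orientation = vapply(out, function(o) o$truth$orientation, character(1L)),
    duration_us = vapply(out, function(o) o$truth$duration_us, numeric(1L)),
    n_samples = vapply(spectra, function(s) length(s$signal), integer(1L)))
  list(spectra = spectra, truth = truth, config = config)
}

#' Simulate a raw current trace with embedded blockade events
#'
#' Builds an open-pore baseline at `open_current_pA` with Gaussian
#' baseline noise and inserts `n_spectra` simulated blockade events at
#' exponentially distributed gaps (current during an event is
#' `I0 - delta_I`).
#'
#' @param config A `simulation_config`.
#' @param baseline_noise_pA Baseline noise SD in pA (default 2).
#' @param gap_mean_us Mean open-pore gap between events in microseconds
#'   (default 5000).
#' @return List with `trace` (a `raw_trace`) and `truth` (data frame:
#'   `index`, `start_index`, `end_index`, `duration_us`, `orientation`).
#' @export
simulate_trace <- function(config, baseline_noise_pA = 2,
                           gap_mean_us = 5000) {
  stopifnot(inherits(config, "simulation_config"))
  events <- if (config$n_spectra > 0)
    lapply(seq_len(config$n_spectra), simulate_nanospectrum, config = config)
  else list()
  with_seed(config$seed, {
    rate <- config$sampling_rate
    gap_samples <- function() max(1L, as.integer(round(
      rexp(1L, 1 / gap_mean_us) * 1e-6 * rate)))
    pieces <- list()
    truth <- list()
    pos <- 0L
    lead <- gap_samples() + as.integer(0.01 * rate)  # generous first baseline
    pieces[[1L]] <- rep(config$open_current_pA, lead)
    pos <- lead
    for (i in seq_along(events)) {
      ev <- events[[i]]$spectrum
      cur <- config$open_current_pA - ev$signal
      pieces[[length(pieces) + 1L]] <- cur
      truth[[i]] <- data.frame(index = i, start_index = pos + 1L,
                               end_index = pos + length(cur),
                               duration_us = ev$duration_us,
                               orientation = events[[i]]$truth$orientation)
      pos <- pos + length(cur)
      g <- gap_samples()
      pieces[[length(pieces) + 1L]] <- rep(config$open_current_pA, g)
      pos <- pos + g
    }
    samples <- unlist(pieces)
    samples <- samples + rnorm(length(samples), 0, baseline_noise_pA)
    list(trace = raw_trace(samples, rate, source_id = "simulated"),
         truth = if (length(truth)) do.call(rbind, truth)
                 else data.frame(index = integer(0L), start_index = integer(0L),
                                 end_index = integer(0L),
                                 duration_us = numeric(0L),
                                 orientation = character(0L)))
  })
}
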