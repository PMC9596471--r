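# End-to-end orchestration: extract/load -> filter -> resample -> orient ->
# consensus (average, then progressive) -> fit scoring model -> theoretical
# spectrum -> DTW alignment -> PCC -> decoy significance.

#' Pipeline configuration
#'
#' Defaults follow the reference analysis: 170 us duration filter, 500
#' resampled points, progressive consensus with t = 50 and u = 30, 1AAV
#' orientation template, 1AAV-P scoring encoding, 10,000 decoys.
#'
#' @param min_duration_us Analysis-time duration filter (default 170).
#' @param m Resample length (default 500).
#' @param consensus_kind `"alignment"` (average then progressive; default)
#'   or `"average"`.
#' @param t,u Progressive-consensus parameters (defaults 50 and 30).
#' @param orientation_encoding Encoding of the orientation template
#'   (default `"1AAV"`).
#' @param scoring_encoding Encoding fitted and used for the final match
#'   and decoys (default `"1AAV-P"`).
#' @param n_decoys Decoy count for significance (default 10000).
#' @param seed RNG seed for the decoys (default 17).
#' @param scoring_model Optional fixed `blockade_model` to score with; when
#'   `NULL` (default) the scoring model is fitted from the consensus.
#' @param table Volume table.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_duration_us = 170, m = 500L,
                            consensus_kind = c("alignment", "average"),
                            t = 50L, u = 30,
                            orientation_encoding = "1AAV",
                            scoring_encoding = "1AAV-P",
                            n_decoys = 10000L, seed = 17L,
                            scoring_model = NULL,
                            table = load_volume_table()) {
  consensus_kind <- match.arg(consensus_kind)
  orientation_encoding <- match_encoding(orientation_encoding)
  scoring_encoding <- match_encoding(scoring_encoding)
  structure(as.list(environment()), class = "pipeline_config")
}

pipeline_stage <- function(report, stage, verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  invisible(report)
}

#' Run the full nanospectral analysis pipeline
#'
#' @param events Input nanospectra: a list of `blockade_event`s (e.g. from
#'   [detect_events()], [read_events()] or [simulate_dataset()]`$spectra`),
#'   or a path to an event TSV.
#' @param peptide Target peptide string.
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress messages (default `TRUE`).
#' @return Object of class `nanospec_run`: list with stage counts
#'   (`n_input`, `n_after_filter`, `n_forward`, `n_backward`),
#'   `pcc_average` and `pcc_alignment` (path PCC of each consensus against
#'   the fitted scoring model's theoretical spectrum; `pcc_alignment` is
#'   `NA` under `consensus_kind = "average"`), `p_value` and
#'   `significance`, the fitted `scoring_model`, both consensus objects,
#'   the final `alignment`, the effective `config` and package `version`.
#' @export
run_pipeline <- function(events, peptide, config = pipeline_config(),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(events) && length(events) == 1L)
    events <- read_events(events)
  n_input <- length(events)
  pipeline_stage(NULL, "input", verbose, "%d nanospectra", n_input)

  events <- filter_by_duration(events, config$min_duration_us)
  n_filtered <- length(events)
  pipeline_stage(NULL, "filter", verbose, "%d kept (duration >= %g us)",
                 n_filtered, config$min_duration_us)
  if (n_filtered == 0L)
    stop("pipeline stage 'filter': no nanospectra pass the duration filter")

  mat <- resample_matrix(events, config$m, normalize = TRUE)

  orientation_template <- theoretical_spectrum(
    peptide, volume_template_model(config$orientation_encoding, config$table),
    config$table, config$m)
  ori <- orient_spectra(mat, orientation_template)
  pipeline_stage(NULL, "orient", verbose, "%d forward, %d backward",
                 ori$n_forward, ori$n_backward)

  cons_avg <- average_consensus(ori$matrix)
  cons <- cons_avg
  if (config$consensus_kind == "alignment") {
    cons <- progressive_consensus(ori$matrix, cons_avg,
                                  t = min(config$t, nrow(ori$matrix)),
                                  u = config$u)
  }
  pipeline_stage(NULL, "consensus", verbose, "%s consensus from %d spectra",
                 cons$kind, cons$n_contributing)

  cv <- znormalize(consensus_values(cons))
  if (is.null(config$scoring_model)) {
    # Fit the scoring model on per-residue data points extracted from the
    # alignment between the consensus and the orientation-template spectrum.
    al0 <- constrained_dtw(cv, znormalize(orientation_template$expanded))
    observed <- extract_residue_datapoints(cv, orientation_template, al0)
    ds <- residue_dataset(peptide, observed, config$scoring_encoding,
                          config$table)
    scoring_model <- fit_blockade_model(ds)
    pipeline_stage(NULL, "model", verbose, "fitted %s on %d residue points",
                   scoring_model$method, length(observed))
  } else {
    scoring_model <- config$scoring_model
    pipeline_stage(NULL, "model", verbose, "using supplied %s model",
                   scoring_model$method)
  }

  th <- theoretical_spectrum(peptide, scoring_model, config$table, config$m)
  te <- znormalize(th$expanded)
  pcc_avg <- constrained_dtw(znormalize(cons_avg$values), te)$pcc
  alignment <- constrained_dtw(cv, te)
  pcc_align <- if (config$consensus_kind == "alignment") alignment$pcc
               else NA_real_
  pipeline_stage(NULL, "align", verbose,
                 "PCC (average) %.4f%s", pcc_avg,
                 if (!is.na(pcc_align)) sprintf(", PCC (alignment) %.4f",
                                                pcc_align) else "")

  sig <- significance_test(cv, peptide, scoring_model,
                           n_decoys = config$n_decoys, seed = config$seed,
                           table = config$table)
  pipeline_stage(NULL, "significance", verbose,
                 "p = %.4g over %d decoys", sig$p_value, sig$n_decoys)

  structure(list(n_input = n_input,
                 n_after_filter = n_filtered,
                 n_forward = ori$n_forward,
                 n_backward = ori$n_backward,
                 pcc_average = pcc_avg,
                 pcc_alignment = pcc_align,
                 p_value = sig$p_value,
                 significance = sig,
                 scoring_model = scoring_model,
                 consensus_average = cons_avg,
                 consensus = cons,
                 alignment = alignment,
                 peptide = peptide,
                 config = config,
                 version = as.character(utils::packageVersion("subnanospec"))),
            class = "nanospec_run")
}

# Orientation template uses a fixed volume-proportional law in the given
# encoding (slope 1 per volume column, position column 0 if present): for
# 1AAV this is the residue-volume profile itself.
volume_template_model <- function(encoding, table = load_volume_table()) {
  encoding <- match_encoding(encoding)
  p <- encoding_ncol(encoding)
  cf <- rep(1, p)
  if (grepl("-P$", encoding)) cf[p] <- 0
  blockade_model(encoding, cf, 0)
}

#' @export
print.nanospec_run <- function(x, ...) {
  cat("nanospectral pipeline run\n")
  cat(sprintf("  peptide: %s (%d residues)\n", x$peptide, nchar(x$peptide)))
  cat(sprintf("  spectra: %d in, %d after %g us filter (%d forward / %d backward)\n",
              x$n_input, x$n_after_filter, x$config$min_duration_us,
              x$n_forward, x$n_backward))
  cat(sprintf("  PCC vs %s model: average %.4f",
              x$scoring_model$method, x$pcc_average))
  if (!is.na(x$pcc_alignment))
    cat(sprintf(", alignment %.4f", x$pcc_alignment))
  cat("\n")
  cat(sprintf("  p-value: %.4g (%d decoys, seed %s)\n", x$p_value,
              x$significance$n_decoys, format(x$config$seed)))
  invisible(x)
}

#' Serialise a pipeline report as JSON
#'
#' Writes the scalar summary of a [run_pipeline()] report (counts, PCCs,
#' p-value, effective parameters, version) for machine consumption.
#'
#' @param run A `nanospec_run`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  cfg <- run$config
  jsonlite::write_json(list(
    n_input = run$n_input,
    n_after_filter = run$n_after_filter,
    n_forward = run$n_forward,
    n_backward = run$n_backward,
    pcc_average = run$pcc_average,
    pcc_alignment = run$pcc_alignment,
    p_value = run$p_value,
    decoy_mean = run$significance$decoy_mean,
    decoy_sd = run$significance$decoy_sd,
    config = list(min_duration_us = cfg$min_duration_us, m = cfg$m,
                  consensus_kind = cfg$consensus_kind, t = cfg$t, u = cfg$u,
                  orientation_encoding = cfg$orientation_encoding,
                  scoring_encoding = cfg$scoring_encoding,
                  n_decoys = cfg$n_decoys, seed = cfg$seed),
    version = run$version), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
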