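# Trace input (ABF / TSV), blockade-event detection and event TSV round trip.
#
# The blockade is defined relative to the open-pore current I0 as
# delta_I = I0 - I, so a translocating molecule produces a dip in the
# measured current and a positive blockade signal.

#' Read an ionic-current trace
#'
#' Reads one acquisition of raw current samples from an Axon Binary Format
#' file (gap-free, single-channel, float data; see [write_abf()]) or from a
#' two-column TSV with header `time_s<TAB>current_pA`.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"abf"` or `"tsv"`.
#' @param voltage Applied bias in volts, stored as metadata.
#' @return An object of class `raw_trace`: list with `samples` (pA),
#'   `sampling_rate` (Hz), `voltage`, `source_id`.
#' @export
read_trace <- function(path, format = c("auto", "abf", "tsv"), voltage = NA_real_) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "abf") "abf" else if (ext %in% c("tsv", "txt")) "tsv"
      else stop(sprintf("cannot infer format from extension '.%s'", ext))
  }
  if (format == "abf") {
    ab <- read_abf(path)
    trace <- raw_trace(ab$samples, ab$sampling_rate, voltage = voltage,
                       source_id = basename(path))
  } else {
    df <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                   error = function(e) stop(sprintf(
                     "cannot parse TSV '%s': %s", path, conditionMessage(e))))
    if (!all(c("time_s", "current_pA") %in% names(df)))
      stop("trace TSV must have header 'time_s\tcurrent_pA'")
    if (nrow(df) == 0L) stop("no samples")
    dt <- diff(df$time_s)
    rate <- if (nrow(df) > 1L) 1 / median(dt) else NA_real_
    if (!is.finite(rate) || rate <= 0) stop("cannot infer sampling rate")
    trace <- raw_trace(df$current_pA, rate, voltage = voltage,
                       source_id = basename(path))
  }
  trace
}

#' Construct a raw trace object
#' @param samples Numeric current samples (pA).
#' @param sampling_rate Samples per second.
#' @param voltage Applied bias (V, metadata).
#' @param source_id Origin identifier.
#' @return Object of class `raw_trace`.
#' @export
raw_trace <- function(samples, sampling_rate, voltage = NA_real_,
                      source_id = "trace") {
  if (length(samples) == 0L) stop("no samples")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 voltage = voltage, source_id = source_id),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("raw_trace '%s': %d samples at %.0f S/s (%.3f s)\n",
              x$source_id, length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  invisible(x)
}

## ---- minimal ABF v1.8 subset (gap-free, one channel, float32 data) -------

abf_field_offsets <- list(
  signature = 0L,          # char[4] "ABF "
  version = 4L,            # float
  operation_mode = 8L,     # int16 (3 = gap-free)
  n_samples = 10L,         # int32 lActualAcqLength
  data_section_ptr = 40L,  # int32, 512-byte blocks
  data_format = 100L,      # int16 (1 = float32)
  n_channels = 120L,       # int16
  sample_interval_us = 122L  # float fADCSampleInterval
)

#' Write a minimal ABF v1.8 file
#'
#' Writes a single-channel gap-free Axon Binary Format v1.8 file with
#' float32 data, using the published v1.8 header offsets. Intended for
#' fixtures and for exporting simulated traces; readable by standard ABF
#' tooling that supports the float data format.
#'
#' @param trace A `raw_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abf <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  header <- raw(2048L)
  put <- function(header, offset, bytes) {
    header[(offset + 1L):(offset + length(bytes))] <- bytes
    header
  }
  header <- put(header, abf_field_offsets$signature, charToRaw("ABF "))
  header <- put(header, abf_field_offsets$version,
                writeBin(1.83, raw(), size = 4L, endian = "little"))
  header <- put(header, abf_field_offsets$operation_mode,
                writeBin(3L, raw(), size = 2L, endian = "little"))
  header <- put(header, abf_field_offsets$n_samples,
                writeBin(length(trace$samples), raw(), size = 4L,
                         endian = "little"))
  header <- put(header, abf_field_offsets$data_section_ptr,
                writeBin(4L, raw(), size = 4L, endian = "little"))
  header <- put(header, abf_field_offsets$data_format,
                writeBin(1L, raw(), size = 2L, endian = "little"))
  header <- put(header, abf_field_offsets$n_channels,
                writeBin(1L, raw(), size = 2L, endian = "little"))
  header <- put(header, abf_field_offsets$sample_interval_us,
                writeBin(1e6 / trace$sampling_rate, raw(), size = 4L,
                         endian = "little"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(header, con)
  writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
  invisible(path)
}

read_abf <- function(path) {
  n_bytes <- file.size(path)
  if (is.na(n_bytes) || n_bytes < 2048L)
    stop(sprintf("truncated ABF '%s': %d bytes, need 2048-byte header",
                 path, ifelse(is.na(n_bytes), 0L, n_bytes)))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, raw(), 2048L)
  get <- function(offset, what, size) {
    readBin(header[(offset + 1L):(offset + size)], what, size = size,
            endian = "little")
  }
  sig <- rawToChar(header[1:4])
  if (sig != "ABF ")
    stop(sprintf("not an ABF v1 file (signature '%s' at byte offset 0)", sig))
  n <- get(abf_field_offsets$n_samples, integer(), 4L)
  fmt <- get(abf_field_offsets$data_format, integer(), 2L)
  nch <- get(abf_field_offsets$n_channels, integer(), 2L)
  dt_us <- get(abf_field_offsets$sample_interval_us, numeric(), 4L)
  if (fmt != 1L)
    stop("unsupported ABF data format (only float32, nDataFormat = 1)")
  if (nch != 1L)
    stop("unsupported ABF channel count (single channel only)")
  if (n < 1L || !is.finite(dt_us) || dt_us <= 0)
    stop("corrupt ABF header: bad sample count or sampling interval")
  ptr <- get(abf_field_offsets$data_section_ptr, integer(), 4L)
  data_offset <- ptr * 512L
  if (n_bytes < data_offset + 4L * n)
    stop(sprintf("truncated ABF '%s': data ends at byte %d, expected %d",
                 path, n_bytes, data_offset + 4L * n))
  seek(con, data_offset)
  samples <- readBin(con, numeric(), n, size = 4L, endian = "little")
  list(samples = samples, sampling_rate = 1e6 / dt_us)
}

#' Write a trace as TSV
#' @param trace A `raw_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  df <- data.frame(time_s = (seq_along(trace$samples) - 1L) / trace$sampling_rate,
                   current_pA = trace$samples)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- event detection ------------------------------------------------------

cusum_changepoint <- function(x) {
  # Most likely single change point of the mean of x: split maximising the
  # between-segment sum-of-squares (equivalent to the CUSUM maximum).
  n <- length(x)
  if (n < 2L) return(1L)
  cs <- cumsum(x)
  tot <- cs[n]
  k <- seq_len(n - 1L)
  stat <- (cs[k] - k * tot / n)^2 / (k * (1 - k / n))
  which.max(stat) + 1L   # first index of the second segment
}

#' Detect blockade events in a current trace
#'
#' Finds maximal runs where the current drops below a running-median
#' open-pore baseline by more than `threshold_sigma` times the noise SD
#' (robustly estimated from the baseline residuals), bridges short
#' sub-threshold gaps, refines each boundary with a CUSUM-style
#' change-point step, and discards events shorter than `min_duration_us`
#' (extraction floor, default 42 us).
#'
#' @param trace A `raw_trace`.
#' @param baseline_window Running-median window in samples (odd; default 501).
#' @param threshold_sigma Detection threshold in noise SDs (default 4).
#' @param min_duration_us Extraction-time duration floor in microseconds
#'   (default 42).
#' @param gap_samples Bridge sub-threshold gaps up to this many samples
#'   (default 5).
#' @param refine_margin Half-width (samples) of the boundary refinement
#'   window (default 8).
#' @return List of `blockade_event` objects, in time order. Each has
#'   `signal` (blockade delta-I = I0 - I, pA, one value per sample),
#'   `time` (s), `start_time` (s), `duration_us`, `open_current` (I0, pA),
#'   `fractional_blockade` (mean delta-I / I0) and `sampling_rate`.
#' @export
detect_events <- function(trace, baseline_window = 501L, threshold_sigma = 4,
                          min_duration_us = 42, gap_samples = 5L,
                          refine_margin = 8L) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$samples
  if (any(!is.finite(x))) stop("non-finite samples in trace")
  if (threshold_sigma <= 0) stop("threshold_sigma must be positive")
  n <- length(x)
  k <- min(as.integer(baseline_window), n)
  if (k %% 2L == 0L) k <- k - 1L
  if (k < 3L || n <= baseline_window)
    stop("trace shorter than baseline window")
  baseline <- runmed(x, k, endrule = "median")
  resid <- x - baseline
  sigma <- mad(resid)
  if (sigma == 0) {
    sigma <- sd(resid)
    if (!is.finite(sigma) || sigma == 0) stop("no baseline")
  }
  dev <- baseline - x                      # positive inside a blockade
  mask <- dev > threshold_sigma * sigma

  r <- rle(mask)
  # bridge short FALSE gaps between detections
  if (length(r$lengths) > 2L) {
    interior <- seq(2L, length(r$lengths) - 1L)
    bridge <- !r$values[interior] & r$lengths[interior] <= gap_samples
    r$values[interior][bridge] <- TRUE
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  events <- list()
  for (ri in runs) {
    s <- starts[ri]; e <- ends[ri]
    # CUSUM boundary refinement within +/- refine_margin of each edge
    lo <- max(1L, s - refine_margin); hi <- min(n, s + refine_margin)
    if (hi - lo >= 2L) s <- lo + cusum_changepoint(x[lo:hi]) - 1L
    lo <- max(1L, e - refine_margin); hi <- min(n, e + refine_margin)
    if (hi - lo >= 2L) e <- lo + cusum_changepoint(x[lo:hi]) - 2L
    if (e < s) next
    dur_us <- (e - s + 1L) / trace$sampling_rate * 1e6
    if (dur_us < min_duration_us) next
    i0 <- median(baseline[s:e])
    ev <- blockade_event(signal = i0 - x[s:e],
                         start_time = (s - 1L) / trace$sampling_rate,
                         open_current = i0,
                         sampling_rate = trace$sampling_rate)
    events[[length(events) + 1L]] <- ev
  }
  events
}

#' Construct a blockade event
#'
#' @param signal Blockade values delta-I = I0 - I (pA), one per sample.
#' @param start_time Event start, seconds from trace start.
#' @param open_current Open-pore current I0 (pA), positive.
#' @param sampling_rate Samples per second.
#' @return Object of class `blockade_event`; `duration_us` is derived from
#'   the sample count and `fractional_blockade` is the mean delta-I / I0.
#' @export
blockade_event <- function(signal, start_time, open_current, sampling_rate) {
  if (open_current <= 0) stop("open_current must be positive")
  signal <- as.numeric(signal)
  structure(list(
    signal = signal,
    time = start_time + (seq_along(signal) - 1L) / sampling_rate,
    start_time = start_time,
    duration_us = length(signal) / sampling_rate * 1e6,
    open_current = open_current,
    fractional_blockade = mean(signal) / open_current,
    sampling_rate = sampling_rate), class = "blockade_event")
}

#' @export
print.blockade_event <- function(x, ...) {
  cat(sprintf(
    "blockade_event: %d samples, duration %.1f us, I0 %.1f pA, dI/I0 %.3f\n",
    length(x$signal), x$duration_us, x$open_current, x$fractional_blockade))
  invisible(x)
}

## ---- heatmap --------------------------------------------------------------

gaussian_smooth2d <- function(z, sigma = 2) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    # reflected-edge 1-D convolution
    n <- length(v)
    vp <- c(rev(v[seq_len(half)]), v, rev(v[n - seq_len(half) + 1L]))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1L):(half + n)]
  }
  z <- apply(z, 2L, smooth1)
  t(apply(z, 1L, smooth1))
}

#' Blockade duration/depth heatmap
#'
#' Bins events over (log10 duration, fractional blockade), smooths the
#' counts with a Gaussian kernel and normalises the grid to total mass 1,
#' giving a discrete probability density over the two descriptors.
#' Fractional blockades are clipped to `[0, 1]` for binning only.
#'
#' @param events List of `blockade_event`s (non-empty).
#' @param bins Bin counts as `c(duration_bins, blockade_bins)`
#'   (default `c(150, 150)`).
#' @param smooth_sigma Gaussian smoothing SD in bins (default 2).
#' @return Object of class `blockade_heatmap`: list with `density`
#'   (matrix summing to 1), `duration_breaks` (log10 us), `frac_breaks`.
#' @export
blockade_heatmap <- function(events, bins = c(150L, 150L), smooth_sigma = 2) {
  if (length(events) == 0L) stop("events must be non-empty")
  bins <- as.integer(bins)
  if (length(bins) != 2L || any(bins < 1L)) stop("bins must be two positive counts")
  dur <- log10(vapply(events, function(e) e$duration_us, numeric(1L)))
  frac <- vapply(events, function(e) e$fractional_blockade, numeric(1L))
  frac <- pmin(pmax(frac, 0), 1)
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r + diff(r) * c(-0.02, 0.02)
  dbr <- seq(pad(range(dur))[1L], pad(range(dur))[2L], length.out = bins[1L] + 1L)
  fbr <- seq(pad(range(frac))[1L], pad(range(frac))[2L], length.out = bins[2L] + 1L)
  di <- pmin(findInterval(dur, dbr, rightmost.closed = TRUE), bins[1L])
  fi <- pmin(findInterval(frac, fbr, rightmost.closed = TRUE), bins[2L])
  z <- matrix(0, bins[1L], bins[2L])
  for (i in seq_along(di)) z[di[i], fi[i]] <- z[di[i], fi[i]] + 1
  if (smooth_sigma > 0 && all(bins >= 3L)) z <- gaussian_smooth2d(z, smooth_sigma)
  z[z < 0] <- 0
  z <- z / sum(z)
  structure(list(density = z, duration_breaks = dbr, frac_breaks = fbr),
            class = "blockade_heatmap")
}

#' @export
#' @method plot blockade_heatmap
plot.blockade_heatmap <- function(x, ...) {
  image(x = x$duration_breaks, y = x$frac_breaks, z = x$density,
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = expression(log[10] ~ Delta * t ~ "(" * mu * "s)"),
        ylab = expression(Delta * I / I[0]), ...)
  invisible(x)
}

## ---- event TSV round trip -------------------------------------------------

#' Write blockade events to TSV
#'
#' One row per sample with columns `event_id`, `start_time_s`,
#' `sample_index`, `blockade_pA`, `open_current_pA`; the shared sampling
#' rate is stored in a leading `#` comment line.
#'
#' @param events List of `blockade_event`s (possibly empty; all events must
#'   share one sampling rate).
#' @param path Output path.
#' @param sampling_rate Rate recorded for an empty event list (default
#'   5e5).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, sampling_rate = 5e5) {
  if (length(events)) {
    rates <- vapply(events, function(e) e$sampling_rate, numeric(1L))
    if (length(unique(rates)) != 1L)
      stop("mixed sampling rates in one event file")
    sampling_rate <- rates[1L]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz\t%.10g", sampling_rate), con)
  writeLines("event_id\tstart_time_s\tsample_index\tblockade_pA\topen_current_pA",
             con)
  for (i in seq_along(events)) {
    e <- events[[i]]
    df <- data.frame(event_id = i,
                     start_time_s = e$start_time,
                     sample_index = seq_along(e$signal),
                     blockade_pA = e$signal,
                     open_current_pA = e$open_current)
    write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read blockade events from TSV
#'
#' Inverse of [write_events()]; a header-only file yields an empty list.
#'
#' @param path Input path.
#' @return List of `blockade_event`s.
#' @export
read_events <- function(path) {
  first <- readLines(path, n = 1L)
  rate <- 5e5
  if (startsWith(first, "#")) {
    parts <- strsplit(sub("^#\\s*", "", first), "\t")[[1L]]
    rate <- as.numeric(parts[length(parts)])
    if (!is.finite(rate) || rate <= 0) stop("bad sampling rate header")
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("event_id", "start_time_s", "sample_index", "blockade_pA",
            "open_current_pA")
  if (!all(need %in% names(df)))
    stop("event TSV must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  lapply(split(df, df$event_id), function(d) {
    d <- d[order(d$sample_index), , drop = FALSE]
    blockade_event(signal = d$blockade_pA,
                   start_time = d$start_time_s[1L],
                   open_current = d$open_current_pA[1L],
                   sampling_rate = rate)
  })
}
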