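test_that("trace TSV reading infers the sampling rate and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\tcurrent_pA", "0\t200", "2e-06\t199", "4e-06\t201"),
             path)
  tr <- read_trace(path)
  expect_s3_class(tr, "raw_trace")
  expect_length(tr$samples, 3L)
  expect_equal(tr$sampling_rate, 5e5)

  writeLines("time_s\tcurrent_pA", path)
  expect_error(read_trace(path), "no samples")
  writeLines(c("a\tb", "0\t1"), path)
  expect_error(read_trace(path), "header")
})

test_that("ABF write-then-read round-trips samples and rate", {
  path <- withr::local_tempfile(fileext = ".abf")
  set.seed(11)
  tr <- raw_trace(round(rnorm(1000, 200, 5), 3), 5e5)
  write_abf(tr, path)
  back <- read_trace(path, "abf")
  # float32 storage: exact for values written from float32-representable
  # inputs up to single precision
  expect_equal(back$samples, tr$samples, tolerance = 1e-6)
  expect_equal(back$sampling_rate, tr$sampling_rate, tolerance = 1e-6)

  # truncation is reported with a byte position
  bytes <- readBin(path, raw(), file.size(path))
  writeBin(bytes[1:3000], path)
  expect_error(read_trace(path, "abf"), "truncated")
  writeBin(as.raw(1:100), path)
  expect_error(read_trace(path, "abf"), "truncated|signature")
})

test_that("event detection recovers injected events with accurate durations", {
  # rectangular dips of known depth/width on a noisy baseline
  set.seed(21)
  n_found <- 0L; n_true <- 0L; dur_err <- c()
  for (rep in 1:10) {
    cfg <- simulation_config(n_spectra = 5L, noise_sd = 0.2, dwell_cv = 0.3,
                             duration_meanlog = log(400), duration_sdlog = 0.3,
                             blockade_mean_pA = 60, blockade_sd_pA = 10,
                             seed = 100L + rep)
    sim <- simulate_trace(cfg, baseline_noise_pA = 2)
    ev <- detect_events(sim$trace, baseline_window = 1001L,
                        threshold_sigma = 5, min_duration_us = 42)
    n_true <- n_true + nrow(sim$truth)
    for (k in seq_len(nrow(sim$truth))) {
      tr_start <- sim$truth$start_index[k]
      hit <- which(vapply(ev, function(e)
        abs(e$start_time * cfg$sampling_rate + 1 - tr_start) <= 10,
        logical(1L)))
      if (length(hit) == 1L) {
        n_found <- n_found + 1L
        dur_err <- c(dur_err, abs(ev[[hit]]$duration_us -
                                    sim$truth$duration_us[k]))
      }
    }
  }
  expect_gte(n_found / n_true, 0.95)
  # duration error within 2 sample periods (2 us at 500 kS/s) for most,
  # and within 10 us always
  expect_gte(mean(dur_err <= 2 * 1e6 / 5e5), 0.9)
  expect_lt(max(dur_err), 10)
})

test_that("flat traces yield no events and degenerate traces error", {
  tr <- raw_trace(rep(200, 5000) + rnorm(5000, 0, 0.5), 5e5)
  expect_length(detect_events(tr, baseline_window = 501L), 0L)
  expect_error(detect_events(raw_trace(rep(0, 5000), 5e5),
                             baseline_window = 501L), "no baseline")
  expect_error(detect_events(raw_trace(c(1, NA, rep(1, 5000)), 5e5),
                             baseline_window = 501L), "non-finite")
  expect_error(detect_events(raw_trace(1:10, 5e5), baseline_window = 501L),
               "shorter")
})

test_that("blockade arithmetic holds sample-wise on detected events", {
  set.seed(3)
  cfg <- simulation_config(n_spectra = 3L, noise_sd = 0.1,
                           duration_meanlog = log(500), duration_sdlog = 0.2,
                           seed = 31L)
  sim <- simulate_trace(cfg, baseline_noise_pA = 1)
  ev <- detect_events(sim$trace, baseline_window = 1001L, threshold_sigma = 5)
  expect_gt(length(ev), 0L)
  for (e in ev) {
    idx <- round(e$start_time * cfg$sampling_rate) + seq_along(e$signal)
    # delta_I = I0 - I exactly, per sample
    expect_equal(e$signal, e$open_current - sim$trace$samples[idx])
    expect_gt(e$open_current, 0)
  }
})

test_that("heatmap density is normalized and concentrated where events are", {
  ev1 <- blockade_event(rep(50, 100), 0, 200, 5e5)
  hm1 <- blockade_heatmap(list(ev1), bins = c(50L, 50L))
  expect_equal(sum(hm1$density), 1, tolerance = 1e-9)
  # duplicated events give the same normalized density
  hm2 <- blockade_heatmap(list(ev1, ev1), bins = c(50L, 50L))
  expect_equal(hm1$density, hm2$density)
  expect_error(blockade_heatmap(list()), "non-empty")
  expect_error(blockade_heatmap(list(ev1), bins = c(0L, 10L)), "positive")

  # spread events cover more of the grid than a point mass
  set.seed(9)
  evs <- lapply(1:200, function(i)
    blockade_event(rnorm(sample(30:300, 1), 50, 5), 0, 200, 5e5))
  hm3 <- blockade_heatmap(evs, bins = c(50L, 50L))
  expect_equal(sum(hm3$density), 1, tolerance = 1e-9)
  entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  expect_gt(entropy(hm3$density), entropy(hm1$density))
})

test_that("event TSV round trip is lossless including the empty case", {
  set.seed(4)
  evs <- lapply(1:4, function(i)
    blockade_event(rnorm(sample(5:50, 1), 40, 6),
                   start_time = runif(1), open_current = 200, sampling_rate = 5e5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(evs, path)
  back <- read_events(path)
  expect_length(back, 4L)
  for (i in seq_along(evs)) {
    expect_equal(back[[i]]$signal, evs[[i]]$signal)
    expect_equal(back[[i]]$start_time, evs[[i]]$start_time)
    expect_equal(back[[i]]$open_current, evs[[i]]$open_current)
    expect_equal(back[[i]]$duration_us, evs[[i]]$duration_us)
  }
  # single event with 5 samples -> comment + header + 5 rows
  write_events(list(blockade_event(1:5, 0, 100, 5e5)), path)
  expect_length(readLines(path), 7L)
  # empty list -> header-only file, accepted on read
  write_events(list(), path)
  expect_length(read_events(path), 0L)
  # mixed rates refuse to serialise
  expect_error(write_events(list(blockade_event(1:5, 0, 100, 5e5),
                                 blockade_event(1:5, 0, 100, 2.5e5)), path),
               "mixed sampling rates")
})
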