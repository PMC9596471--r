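test_that("orientation calls follow the PCC comparison and its tie rule", {
  th <- theoretical_spectrum(peptide_ab42(), m = 200L)
  te <- znormalize(th$expanded)
  expect_equal(assign_orientation(te, th)$orientation, "forward")
  expect_equal(assign_orientation(rev(te), th)$orientation, "backward")
  # exactly palindromic template: tie -> backward with ambiguity flag
  pal <- znormalize(c(1:50, 50:1))
  o <- assign_orientation(pal, pal)
  expect_equal(o$orientation, "backward")
  expect_true(o$ambiguous)
  expect_error(assign_orientation(rep(1, 200), th), "constant")
})

test_that("flipping every input flips every orientation call (involution)", {
  set.seed(30)
  cfg <- noisy_config(40L, noise_sd = 0.5, seed = 33L)
  mat <- resample_matrix(simulate_dataset(cfg)$spectra, 500L)
  th <- theoretical_spectrum(peptide_ab42())
  o1 <- orient_spectra(mat, th)
  o2 <- orient_spectra(mat[, ncol(mat):1], th)
  expect_true(all(o1$orientation != o2$orientation |
                    vapply(seq_len(nrow(mat)), function(i)
                      isTRUE(all.equal(mat[i, ], rev(mat[i, ]))), logical(1L))))
  expect_equal(o1$n_forward, o2$n_backward)
})

test_that("average consensus is the element-wise mean and permutation-invariant", {
  set.seed(31)
  mat <- matrix(rnorm(5 * 20), 5)
  cons <- average_consensus(mat)
  expect_equal(cons$values, colMeans(mat))
  expect_equal(cons$n_contributing, 5L)
  expect_equal(cons$kind, "average")
  expect_equal(average_consensus(mat[sample(5), ])$values, cons$values)
  # single spectrum -> itself; X and -X -> zero
  expect_equal(average_consensus(mat[1, , drop = FALSE])$values, mat[1, ])
  expect_equal(average_consensus(rbind(mat[1, ], -mat[1, ]))$values,
               rep(0, 20))
})

test_that("averaging noisy copies recovers the template better than most
           single spectra", {
  set.seed(32)
  template <- znormalize(expand_to_spectrum(rnorm(42), 500))
  wins <- 0L
  for (r in 1:20) {
    mat <- t(replicate(30, znormalize(template + rnorm(500, 0, 0.8))))
    cons <- average_consensus(mat)
    pcc_cons <- pcc(cons$values, template)
    pcc_single <- apply(mat, 1, pcc, y = template)
    if (pcc_cons > median(pcc_single)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("ranking is by DTW distance with stable ties", {
  set.seed(33)
  template <- znormalize(expand_to_spectrum(rnorm(42), 300))
  noisy <- znormalize(template + rnorm(300, 0, 1.5))
  mat <- rbind(noisy, template, template)
  rk <- rank_by_alignment(mat, template)
  expect_equal(unname(rk$distance[2]), 0)
  expect_equal(rk$order, c(2L, 3L, 1L))   # exact tie keeps input order
  expect_equal(rank_by_alignment(matrix(numeric(0), 0, 300), template)$order,
               integer(0))
})

test_that("progressive consensus has the stated fixed point and weighting", {
  template <- znormalize(expand_to_spectrum(rnorm(42), 200))
  mat <- rbind(template, template, template)
  cons <- progressive_consensus(mat, t = 3L, u = 30)
  expect_equal(cons$values, template, tolerance = 1e-12)  # weighted-mean fixed point
  expect_equal(cons$kind, "alignment")
  expect_equal(cons$weight, 33)

  # t = 1: a diagonal-projected bump moves the consensus by delta / (u + 1)
  delta <- 1e-4                     # small enough to keep the path diagonal
  bumped <- template; bumped[100] <- bumped[100] + delta
  cons1 <- progressive_consensus(rbind(bumped), average_consensus(rbind(template)),
                                 t = 1L, u = 30)
  moved <- cons1$values - template
  expect_equal(moved[100], delta / 31, tolerance = 1e-9)
  expect_equal(max(abs(moved[-100])), 0)
})

test_that("progressive consensus converges to the average as u grows", {
  set.seed(34)
  cfg <- noisy_config(60L, seed = 35L)
  mat <- resample_matrix(filter_by_duration(simulate_dataset(cfg)$spectra, 170),
                         500L)
  avg <- average_consensus(mat)
  prog <- progressive_consensus(mat, avg, t = min(20L, nrow(mat)), u = 1e9)
  expect_lt(max(abs(prog$values - avg$values)), 1e-6)
})

test_that("residue data points are segment means along the path", {
  tab <- load_volume_table()
  th <- theoretical_spectrum(peptide_ab42(), m = 500L)
  te <- znormalize(th$expanded)
  al <- constrained_dtw(te, te)
  obs <- extract_residue_datapoints(te, th, al)
  expect_length(obs, 42L)
  # exact for a linear anchor profile (no curvature): segment mean = anchor
  lin <- theoretical_spectrum("GAV", blockade_model("1AAV", 1, 0), tab, 9L)
  lin$per_residue <- c(1, 2, 3); lin$expanded <- expand_to_spectrum(c(1, 2, 3), 9L)
  ze <- znormalize(lin$expanded)
  obs_lin <- extract_residue_datapoints(ze, lin, constrained_dtw(ze, ze))
  # flat extension compresses the terminal segments equally, so the result
  # stays perfectly linear in the anchors
  expect_equal(pcc(obs_lin, c(1, 2, 3)), 1, tolerance = 1e-9)
  expect_equal(obs_lin[2], 0, tolerance = 1e-9)
  # general case: strong agreement with the generating anchors
  expect_gt(pcc(obs, znormalize(th$per_residue)), 0.95)
})

test_that("noisy consensus still recovers per-residue values", {
  set.seed(36)
  cfg <- noisy_config(150L, noise_sd = 0.3, dwell_cv = 0.2, seed = 37L)
  sim <- simulate_dataset(cfg)
  mat <- resample_matrix(filter_by_duration(sim$spectra, 170), 500L)
  th <- theoretical_spectrum(peptide_ab42())
  ori <- orient_spectra(mat, th)
  cons <- average_consensus(ori$matrix)
  cv <- znormalize(cons$values)
  al <- constrained_dtw(cv, znormalize(th$expanded))
  obs <- extract_residue_datapoints(cv, th, al)
  expect_gte(pcc(obs, znormalize(th$per_residue)), 0.9)
})
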