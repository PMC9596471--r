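test_that("OLS fit matches the normal-equations oracle", {
  set.seed(10)
  tab <- load_volume_table()
  pep <- peptide_ab42()
  X <- encode_peptide(pep, "3AAV", tab)
  beta <- c(0.004, -0.002); alpha <- 0.3
  y <- alpha + X %*% beta + rnorm(42, 0, 0.1)
  ds <- residue_dataset(pep, y, "3AAV", tab)
  m <- fit_blockade_model(ds)
  # direct normal-equations solve
  Xa <- cbind(1, X)
  oracle <- solve(t(Xa) %*% Xa, t(Xa) %*% y)
  expect_equal(unname(c(m$intercept, m$coefficients)), as.numeric(oracle),
               tolerance = 1e-8)
  # residuals orthogonal to the design
  resid <- y - (m$intercept + X %*% m$coefficients)
  expect_lt(max(abs(t(Xa) %*% resid)), 1e-8)
})

test_that("noise-free linear targets are interpolated exactly", {
  tab <- load_volume_table()
  pep <- peptide_ab42()
  X <- encode_peptide(pep, "1AAV-P", tab)
  y <- 0.1 + X %*% c(0.005, -0.02)
  m <- fit_blockade_model(residue_dataset(pep, y, "1AAV-P", tab))
  pred <- predict(m, pep, tab)
  expect_lt(mean((y - pred)^2), 1e-16)
  expect_equal(unname(m$coefficients), c(0.005, -0.02), tolerance = 1e-8)
})

test_that("degenerate designs are rejected with the offending column named", {
  tab <- load_volume_table()
  # homopolymer: volume column is constant, collinear with the intercept
  expect_error(
    fit_blockade_model(residue_dataset(strrep("A", 42), rnorm(42), "1AAV", tab)),
    "collinear.*volume")
})

test_that("two-fold CV pools residuals over both folds", {
  tab <- load_volume_table()
  pepA <- peptide_ab42(); pepB <- peptide_sab42()
  XA <- encode_peptide(pepA, "1AAV", tab)
  XB <- encode_peptide(pepB, "1AAV", tab)
  # identical generating law in both folds, no noise -> zero validation MSE
  law <- function(X) 0.2 + 0.004 * X[, 1]
  cv <- two_fold_cv(residue_dataset(pepA, law(XA), "1AAV", tab),
                    residue_dataset(pepB, law(XB), "1AAV", tab))
  expect_lt(cv$training_mse, 1e-16)
  expect_lt(cv$validation_mse, 1e-12)

  # constant shift between folds under a near-intercept-only design:
  # validation MSE approaches shift^2
  set.seed(11)
  yA <- rep(0.5, 42) + rnorm(42, 0, 1e-9)
  shift <- 0.3
  dsA <- residue_dataset(pepA, yA, "1AAV", tab)
  dsB <- residue_dataset(pepB, yA + shift, "1AAV", tab)
  # same features would be collinear; use the true volume feature but zero
  # effect: fitted slope ~ 0, so prediction ~ fold mean
  cv2 <- two_fold_cv(dsA, dsB)
  expect_equal(cv2$validation_mse, shift^2, tolerance = 0.05)
})

test_that("appending pure-noise feature columns hurts validation error", {
  # 1AAV vs 1AAV plus 3 pure-noise columns, fitted on volume-law targets:
  # the padded design can only overfit
  tab <- load_volume_table()
  pepA <- peptide_ab42(); pepB <- peptide_sab42()
  vA <- znormalize(peptide_volumes(pepA, tab))
  vB <- znormalize(peptide_volumes(pepB, tab))
  pad <- function(ds) {
    ds$features <- cbind(ds$features,
                         noise1 = rnorm(42), noise2 = rnorm(42),
                         noise3 = rnorm(42))
    ds
  }
  wins <- 0L
  set.seed(12)
  for (r in 1:100) {
    yA <- vA + rnorm(42, 0, 0.5)
    yB <- vB + rnorm(42, 0, 0.5)
    dsA <- residue_dataset(pepA, yA, "1AAV", tab)
    dsB <- residue_dataset(pepB, yB, "1AAV", tab)
    lean <- two_fold_cv(dsA, dsB)
    rich <- two_fold_cv(pad(dsA), pad(dsB))
    expect_lte(rich$training_mse, lean$training_mse + 1e-12)
    if (lean$validation_mse <= rich$validation_mse) wins <- wins + 1L
  }
  # With 3 spurious columns the paired inflation has mean k and SD sqrt(6k)
  # per fold, so the per-replicate win probability is ~0.85; 80/100 is a
  # sound lower bound (p < 0.1 of a false alarm) for this construction.
  expect_gte(wins, 80L)
})

test_that("model prediction is linear in the features", {
  tab <- load_volume_table()
  m0 <- blockade_model("1AAV", 0, intercept = 1.5)
  expect_equal(predict(m0, "GAVR", tab), rep(1.5, 4))
  m1 <- blockade_model("1AAV", 1, 0)
  expect_equal(predict(m1, "GAVR", tab), peptide_volumes("GAVR", tab))
  # homopolymer under a position-free method -> constant vector
  expect_equal(diff(predict(m1, "AAAAA", tab)), rep(0, 4))
})

test_that("model JSON round-trips", {
  m <- blockade_model("3AAV-P", c(0.1, -0.2, 0.05), 0.3)
  names(m$coefficients) <- c("volume", "flank_volume", "x_P")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$method, m$method)
})

test_that("expansion interpolates anchors at segment centres", {
  # n=2, m=4: anchors at positions 1 and 3 (centres of segments [0,2), [2,4))
  # grid centres 0.5, 1.5, 2.5, 3.5 -> flat, anchor, interp, flat
  expect_equal(expand_to_spectrum(c(0, 1), 4), c(0, 0.25, 0.75, 1))
  expect_equal(expand_to_spectrum(c(7, 7, 7), 30), rep(7, 30))
  expect_equal(expand_to_spectrum(5, 10), rep(5, 10))
  expect_error(expand_to_spectrum(c(1, 2, 3), 2), "cannot expand")

  # closed-form piecewise-linear oracle on a random case
  set.seed(13)
  v <- rnorm(7); m <- 100L
  anchors <- (seq_along(v) - 0.5) * m / length(v)
  oracle <- sapply(seq_len(m) - 0.5, function(p) {
    if (p <= anchors[1]) return(v[1])
    if (p >= anchors[length(v)]) return(v[length(v)])
    k <- findInterval(p, anchors)
    w <- (p - anchors[k]) / (anchors[k + 1] - anchors[k])
    (1 - w) * v[k] + w * v[k + 1]
  })
  expect_equal(expand_to_spectrum(v, m), oracle, tolerance = 1e-12)
})

test_that("expansion respects range bounds and reversal symmetry", {
  set.seed(14)
  for (r in 1:20) {
    v <- rnorm(sample(2:40, 1))
    m <- sample(length(v):300, 1)
    e <- expand_to_spectrum(v, m)
    expect_gte(min(e), min(v))
    expect_lte(max(e), max(v))
    expect_equal(expand_to_spectrum(rev(v), m), rev(e), tolerance = 1e-12)
  }
})

test_that("coefficients are recovered from a known law as noise vanishes", {
  tab <- load_volume_table()
  pep <- peptide_ab42()
  X <- encode_peptide(pep, "1AAV", tab)
  set.seed(15)
  y <- 0.7 + 0.003 * X[, 1] + rnorm(42, 0, 1e-8)
  m <- fit_blockade_model(residue_dataset(pep, y, "1AAV", tab))
  expect_lt(abs(unname(m$coefficients) - 0.003), 1e-6)
  expect_lt(abs(m$intercept - 0.7), 1e-5)
})
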