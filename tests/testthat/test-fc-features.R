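make_bundle <- function(signal, nets, motion = NULL, tissue = NULL, tr = 2) {
  if (is.null(motion)) motion <- matrix(0, ncol(signal), 6)
  ts_bundle(signal, nets, motion, tissue_means = tissue, tr_seconds = tr)
}

test_that("framewise displacement follows the backward-difference arc-length form", {
  m <- matrix(0, 6, 6)
  expect_equal(framewise_displacement(m), rep(0, 6))
  # additive constant on any trace leaves FD unchanged
  m2 <- sweep(m, 2, c(5, -3, 2, 0.1, 0.2, 0.3), `+`)
  expect_equal(framewise_displacement(m2), rep(0, 6))
  # single 0.6 mm translation step
  m[3:6, 1] <- 0.6
  expect_equal(framewise_displacement(m), c(0, 0, 0.6, 0, 0, 0))
  # 0.012 rad rotation step at 50 mm radius contributes 0.6 mm arc length
  m3 <- matrix(0, 3, 6); m3[2:3, 5] <- 0.012
  expect_equal(framewise_displacement(m3), c(0, 0.012 * 50, 0))
  expect_error(framewise_displacement(matrix(0, 3, 5)), "6 columns")
})

test_that("scrubbing removes exactly the frames above threshold", {
  sig <- matrix(rnorm(8), 2, 4)
  b <- make_bundle(sig, c(1, 1))
  fd <- c(0, 0.6, 0.2, 0.55)
  s <- scrub(b, fd = fd, threshold_mm = 0.5)
  expect_equal(s$kept, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(s$scrub_ratio, 0.5)
  expect_equal(s$bundle$signal, sig[, c(1, 3)])
  expect_true(s$excluded)  # 50% > 40% QC bound

  # all below threshold: identity, ratio 0
  s0 <- scrub(b, fd = rep(0.1, 4))
  expect_equal(s0$scrub_ratio, 0)
  expect_false(s0$excluded)
  expect_equal(s0$bundle$signal, sig)

  # idempotent at fixed threshold
  s1 <- scrub(s$bundle, threshold_mm = 0.5)
  expect_equal(s1$bundle$signal, s$bundle$signal)
  expect_equal(s1$scrub_ratio, 0)

  expect_error(scrub(b, fd = rep(1, 4)), "every frame")
})

test_that("QC exclusion triggers strictly above a 40% scrub ratio", {
  sig <- matrix(rnorm(200), 2, 100)
  b <- make_bundle(sig, c(1, 1))
  fd41 <- c(rep(1, 41), rep(0, 59))
  expect_true(scrub(b, fd = fd41)$excluded)
  fd40 <- c(rep(1, 40), rep(0, 60))
  expect_false(scrub(b, fd = fd40)$excluded)
})

test_that("nuisance regression orthogonalizes voxels against all regressors", {
  set.seed(7)
  nf <- 100
  motion <- matrix(rnorm(nf * 6), nf, 6)
  tissue <- matrix(rnorm(nf * 3), nf, 3)
  sig <- matrix(rnorm(5 * nf), 5, nf)
  sig[1, ] <- motion[, 2]  # voxel equal to a motion trace
  b <- make_bundle(sig, rep(1, 5), motion, tissue)
  r <- nuisance_regress(b)
  expect_lt(max(abs(r$signal[1, ])), 1e-10)
  reg <- cbind(motion, tissue)
  nonzero <- 2:5  # voxel 1's residual is identically zero
  inner <- abs(r$signal[nonzero, ] %*% reg) /
    (sqrt(rowSums(r$signal[nonzero, ]^2)) %o% sqrt(colSums(reg^2)))
  expect_lt(max(inner), 1e-8)
  # residuals also orthogonal to the intercept
  expect_lt(max(abs(rowMeans(r$signal))), 1e-10)

  b2 <- make_bundle(sig, rep(1, 5), motion[, c(1:5, 1)])  # duplicated column
  expect_error(nuisance_regress(b2), "collinear")
})

test_that("regressors orthogonal to the signal leave the de-meaned input unchanged", {
  nf <- 64
  t_ax <- seq_len(nf)
  sig <- matrix(sin(2 * pi * 4 * t_ax / nf), 1, nf)
  # six distinct cosine harmonics, all orthogonal to the signal over nf samples
  motion <- sapply(1:6, function(k) cos(2 * pi * k * t_ax / nf))
  b <- make_bundle(sig, 1L, motion)
  r <- nuisance_regress(b)
  expect_equal(r$signal, sig - rowMeans(sig), tolerance = 1e-10)
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band power", {
  tr <- 0.72
  nf <- 500
  t_sec <- (seq_len(nf) - 1) * tr
  amp <- function(x) stats::sd(x)
  inband <- sin(2 * pi * 0.03 * t_sec)
  outband <- sin(2 * pi * 0.3 * t_sec)  # cardiac-range frequency
  b <- make_bundle(rbind(inband, outband, 1 + 0 * t_sec + rnorm(nf, 0, 1e-8)), c(1, 1, 1), tr = tr)
  f <- bandpass(b)
  expect_gt(amp(f$signal[1, ]) / amp(inband), 0.9)
  expect_lt(amp(f$signal[2, ]) / amp(outband), 0.1)
  # constant (DC) component removed
  expect_lt(amp(f$signal[3, ]), 1e-6)
  expect_error(bandpass(b, 0.1, 0.05), "inverted")
  expect_error(bandpass(make_bundle(matrix(rnorm(40), 1, 40), 1, tr = 10)), "Nyquist")
})

test_that("compute_fc matches construction on identical and independent networks", {
  set.seed(11)
  a2 <- make_atlas(2, 3, seed = 1)
  nf <- 400
  shared <- rnorm(nf)
  # both networks driven by the same mean time course -> between FC 1
  sig <- rbind(matrix(rep(shared, 3), 3, nf, byrow = TRUE) + rnorm(3 * nf, 0, 1e-6),
               matrix(rep(shared, 3), 3, nf, byrow = TRUE) + rnorm(3 * nf, 0, 1e-6))
  fc <- compute_fc(make_bundle(sig, a2$voxel_network), a2)
  expect_equal(length(fc), 3L)
  expect_gt(fc["between.network_01.network_02"], 0.999)
  expect_true(all(fc >= -1 & fc <= 1))

  # independent white-noise networks, many frames -> between FC near 0
  nf2 <- 5000
  sig2 <- matrix(rnorm(6 * nf2), 6, nf2)
  fc2 <- compute_fc(make_bundle(sig2, a2$voxel_network), a2)
  expect_lt(abs(fc2[3]), 0.05)
})

test_that("within-network FC approaches the signal-variance fraction", {
  # voxels = shared signal (var 1) + iid noise (var 1) -> within FC -> 0.5
  set.seed(13)
  a2 <- make_atlas(2, 10, seed = 1)
  nf <- 5000
  s1 <- rnorm(nf); s2 <- rnorm(nf)
  sig <- rbind(matrix(rep(s1, 10), 10, nf, byrow = TRUE) + rnorm(10 * nf),
               matrix(rep(s2, 10), 10, nf, byrow = TRUE) + rnorm(10 * nf))
  fc <- compute_fc(make_bundle(sig, a2$voxel_network), a2)
  expect_equal(unname(fc[1]), 0.5, tolerance = 0.05)
  expect_equal(unname(fc[2]), 0.5, tolerance = 0.05)
})

test_that("compute_fc is invariant to the transforms correlation permits", {
  set.seed(17)
  a2 <- make_atlas(3, 4, seed = 1)
  sig <- matrix(rnorm(12 * 60), 12, 60)
  fc1 <- compute_fc(make_bundle(sig, a2$voxel_network), a2)
  # per-voxel offsets and a shared positive gain per network leave all
  # features unchanged (within: correlation property; between: the network
  # mean is shifted/scaled affinely)
  sig2 <- (sig + rnorm(12)) * rep(c(2, 0.5, 7), each = 4)
  fc2 <- compute_fc(make_bundle(sig2, a2$voxel_network), a2)
  expect_equal(fc1, fc2, tolerance = 1e-12)
  # rescaling a single voxel reweights its network's mean series: the
  # within-network features (pairwise voxel correlations) must still match
  sig3 <- sig
  sig3[5, ] <- 3.7 * sig3[5, ] - 11
  fc3 <- compute_fc(make_bundle(sig3, a2$voxel_network), a2)
  expect_equal(fc1[1:3], fc3[1:3], tolerance = 1e-12)
})

test_that("ICC matches the mean-square oracle, clamps negatives, and is 1 on identical sessions", {
  # identical test/retest -> ICC 1 everywhere
  set.seed(19)
  x <- matrix(rnorm(12), 4, 3)
  r <- icc(x, x)
  expect_equal(r$icc, rep(1, 3))

  # toy 3 subjects x 2 sessions against explicit MS computation
  y <- cbind(c(0, 1, 2), c(0.2, 1.1, 1.9))
  k <- 2; n <- 3
  sm <- rowMeans(y)
  ms_b <- k * sum((sm - mean(y))^2) / (n - 1)
  ms_w <- sum((y - sm)^2) / (n * (k - 1))
  expected <- (ms_b - ms_w) / (ms_b + (k - 1) * ms_w)
  r2 <- icc(matrix(y[, 1]), matrix(y[, 2]))
  expect_equal(r2$icc, expected, tolerance = 1e-12)
  expect_equal(r2$ms_between, ms_b)
  expect_equal(r2$ms_within, ms_w)

  # dominant within-subject variance -> raw ICC negative -> clamped to 0
  # (subject means identical, sessions anticorrelated: MS_b = 0 < MS_w)
  r3 <- icc(matrix(c(0, 1)), matrix(c(1, 0)))
  expect_lt((r3$ms_between - r3$ms_within), 0)
  expect_equal(r3$icc, 0)
  expect_error(icc(matrix(1, 1, 2), matrix(1, 1, 2)), "2 subjects")
})

test_that("ICC on simulated variance components matches the closed form", {
  set.seed(29)
  n <- 200; sb2 <- 1; sw2 <- 0.5
  subj <- rnorm(n, sd = sqrt(sb2))
  s1 <- subj + rnorm(n, sd = sqrt(sw2))
  s2 <- subj + rnorm(n, sd = sqrt(sw2))
  r <- icc(matrix(s1), matrix(s2))
  expect_equal(r$icc, sb2 / (sb2 + sw2), tolerance = 0.1)
})
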