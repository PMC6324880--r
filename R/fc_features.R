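#' Bundle a voxel time-series matrix with its realignment parameters
#'
#' Container for one subject's realigned resting-state data: a voxel x frame
#' signal matrix, the voxel -> network map, the six realignment parameters per
#' frame (three translations in mm, three rotations in radians) and optional
#' per-frame mean tissue signals (gray matter, white matter, CSF) used as
#' nuisance regressors.
#'
#' @param signal numeric matrix, voxels x frames.
#' @param voxel_network integer vector, length `nrow(signal)`; network id per voxel.
#' @param motion numeric matrix, frames x 6 (tx, ty, tz in mm; rx, ry, rz in rad).
#' @param tissue_means optional numeric matrix, frames x 3 (GM, WM, CSF means).
#' @param tr_seconds repetition time in seconds.
#' @return object of class `ts_bundle`.
#' @export
ts_bundle <- function(signal, voxel_network, motion, tissue_means = NULL,
                      tr_seconds = 2) {
  signal <- as.matrix(signal)
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns (3 translations, 3 rotations)")
  if (nrow(motion) != ncol(signal))
    stop("frame counts of `signal` and `motion` disagree")
  if (length(voxel_network) != nrow(signal))
    stop("`voxel_network` must map every voxel (row of `signal`)")
  if (!is.null(tissue_means)) {
    tissue_means <- as.matrix(tissue_means)
    if (nrow(tissue_means) != ncol(signal))
      stop("frame counts of `signal` and `tissue_means` disagree")
  }
  structure(list(signal = signal, voxel_network = as.integer(voxel_network),
                 motion = motion, tissue_means = tissue_means,
                 tr_seconds = tr_seconds),
            class = "ts_bundle")
}

#' @export
print.ts_bundle <- function(x, ...) {
  cat(sprintf("ts_bundle: %d voxels x %d frames, %d networks, TR %.3g s\n",
              nrow(x$signal), ncol(x$signal), length(unique(x$voxel_network)),
              x$tr_seconds))
  invisible(x)
}

#' Framewise displacement from realignment parameters
#'
#' Power-style FD: the sum of absolute backward differences of the six
#' realignment parameters, with the three rotations converted to arc length on
#' a sphere of radius `head_radius_mm`. The first frame has FD 0 by convention.
#'
#' @param motion frames x 6 matrix (translations mm, rotations rad) or a
#'   `ts_bundle`.
#' @param head_radius_mm radius used to convert rotations to mm (default 50).
#' @return numeric vector of per-frame FD in mm.
#' @examples
#' m <- matrix(0, 5, 6); m[3, 1] <- 0.6
#' framewise_displacement(m)  # 0 0 0.6 0.6 0
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  if (inherits(motion, "ts_bundle")) motion <- motion$motion
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("`motion` must have 6 columns")
  if (nrow(motion) < 1L) stop("`motion` needs at least one frame")
  scaled <- motion
  scaled[, 4:6] <- scaled[, 4:6] * head_radius_mm
  if (nrow(scaled) == 1L) return(0)
  d <- abs(diff(scaled))
  c(0, rowSums(d))
}

#' Remove high-motion frames (scrubbing)
#'
#' Frames whose FD exceeds `threshold_mm` are dropped from the signal, motion
#' and tissue traces; neighbouring frames are retained. The fraction of frames
#' removed is reported, together with a QC flag marking subjects whose removed
#' fraction exceeds `qc_max_ratio` as unusable.
#'
#' @param bundle a `ts_bundle`.
#' @param fd per-frame FD; computed from the bundle's motion if missing.
#' @param threshold_mm scrub threshold (default 0.5 mm).
#' @param qc_max_ratio maximum tolerable removed fraction (default 0.40).
#' @return list with `bundle` (scrubbed), `kept` (logical per original frame),
#'   `scrub_ratio` and `excluded` (TRUE when `scrub_ratio > qc_max_ratio`).
#' @export
scrub <- function(bundle, fd = NULL, threshold_mm = 0.5, qc_max_ratio = 0.40) {
  stopifnot(inherits(bundle, "ts_bundle"))
  if (is.null(fd)) fd <- framewise_displacement(bundle)
  if (length(fd) != ncol(bundle$signal))
    stop("`fd` length must equal the frame count")
  kept <- fd <= threshold_mm
  if (!any(kept)) stop("scrubbing removed every frame; subject unusable")
  ratio <- mean(!kept)
  out <- bundle
  out$signal <- bundle$signal[, kept, drop = FALSE]
  out$motion <- bundle$motion[kept, , drop = FALSE]
  if (!is.null(bundle$tissue_means))
    out$tissue_means <- bundle$tissue_means[kept, , drop = FALSE]
  list(bundle = out, kept = kept, scrub_ratio = ratio,
       excluded = ratio > qc_max_ratio)
}

#' Regress nuisance signals out of every voxel time series
#'
#' Removes the six realignment parameters and (when present) the mean gray
#' matter, white matter and CSF signals, plus an intercept, from each voxel's
#' time course by ordinary least squares. Residuals are orthogonal to every
#' regressor.
#'
#' @param bundle a `ts_bundle`.
#' @return the bundle with `signal` replaced by residuals.
#' @export
nuisance_regress <- function(bundle) {
  stopifnot(inherits(bundle, "ts_bundle"))
  X <- cbind(bundle$motion, bundle$tissue_means)
  colnames(X) <- c(paste0("motion_", 1:6),
                   if (!is.null(bundle$tissue_means)) c("gm", "wm", "csf"))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  keep <- apply(Xc, 2L, function(v) any(v != 0))  # constant columns = intercept
  Xc <- Xc[, keep, drop = FALSE]
  if (ncol(Xc) > 0L) {
    qrX <- qr(Xc)
    if (qrX$rank < ncol(Xc)) {
      bad <- colnames(Xc)[setdiff(seq_len(ncol(Xc)), qrX$pivot[seq_len(qrX$rank)])]
      stop("nuisance regressors are collinear: ", paste(bad, collapse = ", "))
    }
    res <- t(qr.resid(qrX, t(bundle$signal - rowMeans(bundle$signal))))
  } else {
    res <- bundle$signal - rowMeans(bundle$signal)
  }
  bundle$signal <- res
  bundle
}

#' Band-pass filter voxel time series
#'
#' Ideal (FFT-mask) band-pass retaining frequencies in `[low_hz, high_hz]`,
#' used in the high-temporal-resolution processing profile to isolate slow
#' spontaneous fluctuations and suppress high-frequency physiological noise
#' (e.g. cardiac pulsation near 0.3 Hz). The DC component is removed.
#'
#' @param bundle a `ts_bundle` with known `tr_seconds`.
#' @param low_hz,high_hz band edges in Hz (defaults 0.009 and 0.08).
#' @return the bundle with filtered `signal`.
#' @export
bandpass <- function(bundle, low_hz = 0.009, high_hz = 0.08) {
  stopifnot(inherits(bundle, "ts_bundle"))
  if (low_hz >= high_hz) stop("band edges inverted: `low_hz` must be < `high_hz`")
  nyquist <- 1 / (2 * bundle$tr_seconds)
  if (high_hz >= nyquist)
    stop(sprintf("`high_hz` (%.3g Hz) must be below Nyquist (%.3g Hz)", high_hz, nyquist))
  nf <- ncol(bundle$signal)
  freqs <- (seq_len(nf) - 1L) / (nf * bundle$tr_seconds)
  freqs <- pmin(freqs, 1 / bundle$tr_seconds - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  ft <- t(stats::mvfft(t(bundle$signal)))
  ft[, !keep] <- 0
  bundle$signal <- Re(t(stats::mvfft(t(ft), inverse = TRUE))) / nf
  bundle
}

#' Network-level functional connectivity vector
#'
#' Between-network FC is the Pearson correlation between network-mean time
#' courses; within-network FC is the mean of all pairwise voxel correlations
#' inside the network. Values are returned in the canonical feature order
#' (within features for networks 1..n, then between pairs (i, j), i < j).
#'
#' @param bundle a `ts_bundle` (after any scrubbing/nuisance regression).
#' @param atlas a `wma_atlas`; its network count must match the bundle's
#'   `voxel_network` labels.
#' @return named numeric vector of length [n_fc_features()].
#' @export
compute_fc <- function(bundle, atlas) {
  stopifnot(inherits(bundle, "ts_bundle"), inherits(atlas, "wma_atlas"))
  n <- atlas$n_networks
  if (ncol(bundle$signal) < 3L) stop("need at least 3 frames to estimate FC")
  nets <- sort(unique(bundle$voxel_network))
  if (!identical(nets, seq_len(n)))
    stop("bundle voxel_network labels must cover networks 1..", n)

  sig <- bundle$signal
  # drop zero-variance voxels (correlation undefined)
  v <- apply(sig, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance voxel(s) dropped before correlation")
    keep <- v > 0
    if (any(tapply(keep, bundle$voxel_network, sum) < 2L))
      stop("a network has fewer than 2 usable voxels after dropping constants")
    sig <- sig[keep, , drop = FALSE]
    voxnet <- bundle$voxel_network[keep]
  } else voxnet <- bundle$voxel_network

  within <- numeric(n)
  means <- matrix(0, ncol(sig), n)
  for (k in seq_len(n)) {
    vox <- t(sig[voxnet == k, , drop = FALSE])
    cm <- stats::cor(vox)
    within[k] <- mean(cm[upper.tri(cm)])
    means[, k] <- rowMeans(vox)
  }
  if (any(apply(means, 2L, stats::var) == 0))
    stop("zero-variance network mean series for network(s): ",
         paste(which(apply(means, 2L, stats::var) == 0), collapse = ", "))
  cmat <- stats::cor(means)
  between <- cmat[upper.tri(cmat)]
  # upper.tri extracts column-major; reorder to lexicographic (i, j), i<j
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  between <- between[order(idx[, 1L], idx[, 2L])]
  fc <- c(within, between)
  names(fc) <- fc_feature_labels(atlas)
  fc
}

#' Test-retest intraclass correlation of FC features
#'
#' One-way random-effects ICC per feature from two (or more) sessions:
#' `ICC = (MS_b - MS_w) / (MS_b + (k - 1) MS_w)`, where `MS_b` and `MS_w` are
#' the between- and within-subject mean squares and `k` the number of
#' sessions. Negative values are clamped to zero.
#'
#' @param test_fc,retest_fc subjects x features matrices with matching
#'   dimensions (rows are the same subjects).
#' @param ... further sessions (same shape) for k > 2.
#' @return object of class `icc_result`: data.frame with `feature`, `ms_between`,
#'   `ms_within`, `icc`, plus attributes `k`, `mean`, `sd`.
#' @export
icc <- function(test_fc, retest_fc, ...) {
  sessions <- c(list(as.matrix(test_fc), as.matrix(retest_fc)),
                lapply(list(...), as.matrix))
  dims <- vapply(sessions, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all sessions must have identical subjects x features dimensions")
  ns <- dims[1, 1]; p <- dims[2, 1]; k <- length(sessions)
  if (ns < 2L) stop("ICC needs at least 2 subjects")

  ms_b <- ms_w <- icc_raw <- numeric(p)
  for (j in seq_len(p)) {
    y <- vapply(sessions, function(s) s[, j], numeric(ns))  # subjects x k
    sub_means <- rowMeans(y)
    ms_b[j] <- k * sum((sub_means - mean(y))^2) / (ns - 1)
    ms_w[j] <- sum((y - sub_means)^2) / (ns * (k - 1))
    icc_raw[j] <- (ms_b[j] - ms_w[j]) / (ms_b[j] + (k - 1) * ms_w[j])
  }
  icc_clamped <- pmax(icc_raw, 0)
  feats <- colnames(sessions[[1L]])
  if (is.null(feats)) feats <- sprintf("feature_%03d", seq_len(p))
  out <- data.frame(feature = feats, ms_between = ms_b, ms_within = ms_w,
                    icc = icc_clamped, stringsAsFactors = FALSE)
  structure(out, k = k, mean = mean(icc_clamped), sd = stats::sd(icc_clamped),
            class = c("icc_result", "data.frame"))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC over %d features (k = %d): %.3f +/- %.3f (range %.3f to %.3f)\n",
              nrow(x), attr(x, "k"), attr(x, "mean"), attr(x, "sd"),
              min(x$icc), max(x$icc)))
  invisible(x)
}
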