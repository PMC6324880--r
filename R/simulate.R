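.known_diagnoses <- c("HC", "SCZ", "MDD", "OCD", "ASD")

#' Ground truth for synthetic cohorts
#'
#' Defines the generative FC -> WMA relation used by [simulate_cohort()]: a
#' sparse weight vector over the canonical FC features, an intercept,
#' residual noise, per-diagnosis FC mean shifts, and couplings linking the
#' confound variables to true WMA.
#'
#' @param atlas a `wma_atlas`.
#' @param n_nonzero number of nonzero weights (default 16, the size of the
#'   normative model's selected-connection set).
#' @param w_scale scale of the nonzero weights (drawn from
#'   +/- Uniform(0.5, 1.5) * `w_scale`).
#' @param intercept true intercept (d-prime units, default 2).
#' @param noise_sd residual SD of WMA given FC (default 0.1).
#' @param fc_sd between-subject SD of each FC feature (default 0.1).
#' @param fc_mean optional population mean FC vector; by default within
#'   features centre near 0.5 and between features near 0.1.
#' @param deltas named list (diagnosis -> per-feature FC shift vector); the HC
#'   shift is always zero. See [delta_for_effect()] to plant a target
#'   Hedges' g.
#' @param confound_coupling named numeric: correlations of fluid
#'   intelligence, composite cognition, age and head motion with true WMA.
#' @param seed integer seed (drives weight placement and `fc_mean`).
#' @return object of class `wma_ground_truth`.
#' @export
ground_truth <- function(atlas, n_nonzero = 16L, w_scale = 1, intercept = 2,
                         noise_sd = 0.1, fc_sd = 0.1, fc_mean = NULL,
                         deltas = list(),
                         confound_coupling = c(fluid_intelligence = 0.5,
                                               composite = 0.5,
                                               age = -0.2, motion = -0.3),
                         seed = 1L) {
  stopifnot(inherits(atlas, "wma_atlas"))
  if (noise_sd < 0 || fc_sd < 0) stop("noise SDs must be >= 0")
  p <- n_fc_features(atlas)
  if (n_nonzero < 1L || n_nonzero > p) stop("`n_nonzero` out of range")
  set.seed(seed)
  support <- sort(sample.int(p, n_nonzero))
  w <- numeric(p)
  w[support] <- sample(c(-1, 1), n_nonzero, replace = TRUE) *
    stats::runif(n_nonzero, 0.5, 1.5) * w_scale
  names(w) <- fc_feature_labels(atlas)
  if (is.null(fc_mean)) {
    n <- atlas$n_networks
    fc_mean <- c(stats::runif(n, 0.4, 0.6),
                 stats::runif(p - n, -0.1, 0.3))
    names(fc_mean) <- names(w)
  }
  if (length(fc_mean) != p) stop("`fc_mean` must have one value per FC feature")
  bad <- setdiff(names(deltas), .known_diagnoses)
  if (length(bad)) stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  deltas <- lapply(deltas, function(d) {
    if (length(d) == 1L) d <- rep(d, p)
    if (length(d) != p) stop("each delta must have one shift per FC feature")
    d
  })
  deltas$HC <- numeric(p)
  structure(list(w_true = w, support = support, intercept_true = intercept,
                 noise_sd = noise_sd, fc_sd = fc_sd, fc_mean = fc_mean,
                 delta = deltas, confound_coupling = confound_coupling,
                 seed = as.integer(seed)),
            class = "wma_ground_truth")
}

#' @export
print.wma_ground_truth <- function(x, ...) {
  cat(sprintf("wma_ground_truth: %d/%d nonzero weights, intercept %.3g, noise_sd %.3g, deltas for %s\n",
              length(x$support), length(x$w_true), x$intercept_true,
              x$noise_sd, paste(names(x$delta), collapse = "/")))
  invisible(x)
}

#' Population SD of true WMA under a ground truth
#'
#' With independent feature noise of SD `fc_sd`, `var(w . fc) = fc_sd^2 |w|^2`
#' and the residual adds `noise_sd^2`.
#'
#' @param gt a `wma_ground_truth`.
#' @return scalar SD of `wma_true` in the healthy population.
#' @export
wma_population_sd <- function(gt) {
  sqrt(gt$fc_sd^2 * sum(gt$w_true^2) + gt$noise_sd^2)
}

#' FC shift planting a target Hedges' g on true WMA
#'
#' Returns the per-feature mean shift `delta = g * sd(WMA) * w / |w|^2`, so
#' that `w . delta = g * sd(WMA)`: patients' true WMA shifts by `g` control
#' SDs, planting a population Hedges' g of `g` versus unshifted controls.
#'
#' @param gt a `wma_ground_truth`.
#' @param g target standardized mean difference (patients minus controls).
#' @return numeric shift vector (length = number of FC features).
#' @export
delta_for_effect <- function(gt, g) {
  stopifnot(inherits(gt, "wma_ground_truth"))
  g * wma_population_sd(gt) * gt$w_true / sum(gt$w_true^2)
}

# repair a correlation matrix to PSD: clip eigenvalues, renormalize diagonal
.repair_psd <- function(R, clip = 1e-10) {
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) < clip) {
    warning(sprintf("target network covariance not PSD (min eigenvalue %.3g); clipping",
                    min(eg$values)))
    vals <- pmax(eg$values, clip)
    R <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    check <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (check < -1e-8)
      stop(sprintf("network covariance irreparably non-PSD (eigenvalue %.3g after repair)", check))
  }
  R
}

#' Simulate one subject's voxel time series realizing a target FC vector
#'
#' Network-mean structure comes from latent network factors drawn with the
#' covariance implied by the target between-network correlations (eigenvalue
#' clipping repairs non-PSD targets); within-network FC is controlled by the
#' voxel noise-to-signal ratio, using the closed form
#' `mean pairwise voxel r = var_signal / (var_signal + var_noise)`. A small
#' random-walk motion trace is generated, with sustained displacement steps
#' injected at `spike_frames` so framewise displacement exceeds threshold at
#' exactly those frames.
#'
#' @param atlas a `wma_atlas`.
#' @param target_fc FC vector in canonical order (values in (-1, 1)).
#' @param n_frames number of frames (>= 30).
#' @param tr_seconds repetition time (default 2).
#' @param motion_level SD of per-frame realignment increments in mm
#'   (default 0.01).
#' @param spike_frames frames at which motion steps are injected.
#' @param spike_amplitude step size in mm (default 1).
#' @param seed integer seed.
#' @return a [ts_bundle()] (no tissue means).
#' @export
simulate_subject_timeseries <- function(atlas, target_fc, n_frames = 200L,
                                        tr_seconds = 2, motion_level = 0.01,
                                        spike_frames = integer(0),
                                        spike_amplitude = 1, seed = 1L) {
  stopifnot(inherits(atlas, "wma_atlas"))
  p <- n_fc_features(atlas)
  if (length(target_fc) != p) stop("`target_fc` must have one value per FC feature")
  if (n_frames < 30L) stop("`n_frames` must be >= 30")
  if (any(abs(target_fc) >= 1)) stop("`target_fc` values must lie in (-1, 1)")
  n <- atlas$n_networks
  set.seed(seed)

  R <- diag(n)
  tab <- fc_feature_table(atlas)
  btab <- tab[tab$type == "between", ]
  R[cbind(btab$net_i, btab$net_j)] <- target_fc[btab$index]
  R[cbind(btab$net_j, btab$net_i)] <- target_fc[btab$index]
  R <- .repair_psd(R)
  eg <- eigen(R, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
  factors <- matrix(stats::rnorm(n_frames * n), n_frames, n) %*% t(L)

  within <- pmin(pmax(target_fc[seq_len(n)], 0.02), 0.999)
  noise_sd <- sqrt((1 - within) / within)   # signal variance 1 per factor
  nv <- atlas$voxels_per_network
  signal <- matrix(0, sum(nv), n_frames)
  row <- 0L
  for (k in seq_len(n)) {
    vox <- matrix(factors[, k], nv[k], n_frames, byrow = TRUE) +
      matrix(stats::rnorm(nv[k] * n_frames, 0, noise_sd[k]), nv[k], n_frames)
    signal[row + seq_len(nv[k]), ] <- vox
    row <- row + nv[k]
  }

  motion <- apply(matrix(stats::rnorm(n_frames * 6, 0, motion_level), n_frames, 6),
                  2L, cumsum)
  if (length(spike_frames)) {
    if (any(spike_frames < 2L | spike_frames > n_frames))
      stop("`spike_frames` must lie in 2..n_frames")
    for (f in spike_frames)
      motion[f:n_frames, 1L] <- motion[f:n_frames, 1L] + spike_amplitude
  }
  ts_bundle(signal, atlas$voxel_network, motion, tr_seconds = tr_seconds)
}

#' Simulate a diagnosed cohort with planted FC -> WMA ground truth
#'
#' Generative model, per subject of diagnosis d:
#' `fc = fc_mean + delta[d] + N(0, fc_sd^2 I)` (clipped to (-1, 1)),
#' `wma_true = intercept + w_true . fc + N(0, noise_sd^2)`,
#' `score = wma_true + N(0, score_noise_sd^2)` (the behavioral measurement),
#' and confounds (fluid intelligence, composite cognition, age, head motion)
#' correlated with true WMA at the couplings recorded in the ground truth.
#'
#' @param n_per_group named integer vector: diagnosis -> group size (labels
#'   among HC/SCZ/MDD/OCD/ASD; each >= 2).
#' @param gt a [ground_truth()].
#' @param atlas the `wma_atlas` the ground truth was built on.
#' @param site_map optional named character: diagnosis -> site label
#'   (default: all "site1").
#' @param site_effects optional named list: site -> additive FC offset vector
#'   (default none; population FC means are site-invariant).
#' @param score_noise_sd measurement noise SD on the behavioral score
#'   (default 0.1).
#' @param emit "fc_only" (default) or "timeseries" (additionally simulates a
#'   voxel time-series bundle per subject; slow, for small cohorts).
#' @param n_frames,tr_seconds time-series parameters when
#'   `emit = "timeseries"`.
#' @param seed integer seed.
#' @return list with `cohort` (data.frame: subject_id, diagnosis, site, age,
#'   sex, fluid_intelligence, composite_score, head_motion, score, wma_true),
#'   `fc` (subjects x features matrix, canonical labels), `bundles` (list of
#'   `ts_bundle` or NULL) and `ground_truth`.
#' @export
simulate_cohort <- function(n_per_group, gt, atlas, site_map = NULL,
                            site_effects = NULL, score_noise_sd = 0.1,
                            emit = c("fc_only", "timeseries"),
                            n_frames = 200L, tr_seconds = 2, seed = 1L) {
  emit <- match.arg(emit)
  stopifnot(inherits(gt, "wma_ground_truth"), inherits(atlas, "wma_atlas"))
  diagnoses <- names(n_per_group)
  if (is.null(diagnoses)) stop("`n_per_group` must be named by diagnosis")
  bad <- setdiff(diagnoses, .known_diagnoses)
  if (length(bad)) stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  if (any(n_per_group < 2L)) stop("every group needs n >= 2")
  p <- length(gt$w_true)
  if (p != n_fc_features(atlas)) stop("ground truth and atlas disagree on feature count")
  if (is.null(site_map)) site_map <- stats::setNames(rep("site1", length(diagnoses)),
                                                     diagnoses)
  set.seed(seed)

  rows <- list(); fcs <- list()
  cc <- gt$confound_coupling
  mix <- function(coupling, z, n) {
    coupling <- max(min(coupling, 1), -1)
    coupling * z + sqrt(1 - coupling^2) * stats::rnorm(n)
  }
  sd_wma <- wma_population_sd(gt)
  sid <- 0L
  for (d in diagnoses) {
    n <- n_per_group[[d]]
    delta <- if (!is.null(gt$delta[[d]])) gt$delta[[d]] else numeric(p)
    site <- site_map[[d]]
    off <- if (!is.null(site_effects[[site]])) site_effects[[site]] else numeric(p)
    fc <- matrix(stats::rnorm(n * p, 0, gt$fc_sd), n, p, byrow = FALSE)
    fc <- sweep(fc, 2L, gt$fc_mean + delta + off, `+`)
    fc <- pmin(pmax(fc, -0.999), 0.999)
    wma <- gt$intercept_true + as.numeric(fc %*% gt$w_true) +
      stats::rnorm(n, 0, gt$noise_sd)
    z <- (wma - gt$intercept_true - sum(gt$w_true * (gt$fc_mean + delta + off))) /
      sd_wma
    rows[[d]] <- data.frame(
      subject_id = sprintf("sub-%04d", sid + seq_len(n)),
      diagnosis = d, site = site,
      age = round(35 + 8 * mix(cc[["age"]], z, n)),
      sex = sample(c("M", "F"), n, replace = TRUE),
      fluid_intelligence = 16 + 4 * mix(cc[["fluid_intelligence"]], z, n),
      composite_score = 50 + 10 * mix(cc[["composite"]], z, n),
      head_motion = pmax(0.12 + 0.05 * mix(cc[["motion"]], z, n), 0.01),
      score = wma + stats::rnorm(n, 0, score_noise_sd),
      wma_true = wma, stringsAsFactors = FALSE)
    fcs[[d]] <- fc
    sid <- sid + n
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  fc <- do.call(rbind, fcs)
  dimnames(fc) <- list(cohort$subject_id, fc_feature_labels(atlas))

  bundles <- NULL
  if (emit == "timeseries") {
    bundles <- lapply(seq_len(nrow(fc)), function(i)
      simulate_subject_timeseries(atlas, pmin(pmax(fc[i, ], -0.95), 0.95),
                                  n_frames = n_frames, tr_seconds = tr_seconds,
                                  seed = seed + i))
    names(bundles) <- cohort$subject_id
  }
  list(cohort = cohort, fc = fc, bundles = bundles, ground_truth = gt)
}

#' Simulate per-session 3-back learning curves
#'
#' Session-wise d-prime follows the inverse curve `y = a - b/x` plus Gaussian
#' noise. Optionally each session is realized at the trial level: hit and
#' false-alarm probabilities are the equal-bias rates `pnorm(y/2)` and
#' `pnorm(-y/2)`, drawn binomially over the session's target and non-target
#' trials, so the empirical session d-prime reproduces `y` up to binomial
#' error. Latent d-primes outside the range resolvable by the trial design
#' (via the 1/(2N) correction) trigger a warning and are clipped.
#'
#' @param a plateau per subject (vector).
#' @param b learning-speed parameter per subject (recycled; all >= 0).
#' @param n_sessions number of sessions (>= 3, default 25).
#' @param trials_per_session trials per session (default 60; one third
#'   targets).
#' @param noise_sd session-level d-prime noise SD (default 0.1).
#' @param emit_trials also draw trial-level counts (default FALSE).
#' @param seed integer seed.
#' @return list with `y` (subjects x sessions d-prime matrix) and `trials`
#'   (long data.frame with hits/misses/false_alarms/correct_rejections and
#'   the empirical `dprime`, or NULL).
#' @export
simulate_learning_curves <- function(a, b, n_sessions = 25L,
                                     trials_per_session = 60L, noise_sd = 0.1,
                                     emit_trials = FALSE, seed = 1L) {
  if (n_sessions < 3L) stop("`n_sessions` must be >= 3")
  if (any(b < 0)) stop("`b` must be >= 0")
  ns <- max(length(a), length(b))
  a <- rep_len(a, ns); b <- rep_len(b, ns)
  set.seed(seed)
  x <- seq_len(n_sessions)
  y <- t(vapply(seq_len(ns), function(s)
    a[s] - b[s] / x + stats::rnorm(n_sessions, 0, noise_sd), numeric(n_sessions)))
  rownames(y) <- sprintf("sub-%04d", seq_len(ns))
  colnames(y) <- sprintf("session_%02d", x)

  trials <- NULL
  if (emit_trials) {
    n_t <- round(trials_per_session / 3)
    n_n <- trials_per_session - n_t
    dmax <- stats::qnorm(1 - 1 / (2 * n_t)) - stats::qnorm(1 / (2 * n_n))
    if (any(y > dmax) || any(y < -dmax)) {
      warning("latent d-prime outside the range attainable with ",
              trials_per_session, " trials; clipping")
      y <- pmin(pmax(y, -dmax), dmax)
    }
    grid <- expand.grid(subject = seq_len(ns), session = x)
    d <- y[cbind(grid$subject, grid$session)]
    hits <- stats::rbinom(nrow(grid), n_t, stats::pnorm(d / 2))
    fas <- stats::rbinom(nrow(grid), n_n, stats::pnorm(-d / 2))
    trials <- data.frame(subject = rownames(y)[grid$subject],
                         session = grid$session,
                         hits = hits, misses = n_t - hits,
                         false_alarms = fas, correct_rejections = n_n - fas,
                         stringsAsFactors = FALSE)
    trials$dprime <- dprime(trials$hits, trials$misses, trials$false_alarms,
                            trials$correct_rejections)
    trials <- trials[order(trials$subject, trials$session), ]
    rownames(trials) <- NULL
  }
  list(y = y, trials = trials)
}
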