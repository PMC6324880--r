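#' Partial correlation controlling for confounds
#'
#' Pearson: both variables are residualized on the confound matrix (with an
#' intercept) and the residuals correlated. Spearman: all variables (including
#' confounds) are rank-transformed first, then treated as Pearson — the usual
#' rank-partial convention for non-normal scores.
#'
#' @param a,b numeric vectors of equal length.
#' @param confounds optional numeric matrix/data.frame of confounds (columns),
#'   same number of rows; `NULL` gives the plain correlation.
#' @param method "pearson" or "spearman".
#' @return the partial correlation coefficient.
#' @export
partial_correlation <- function(a, b, confounds = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("`a` and `b` lengths differ")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != length(a)) stop("confound rows must match `a`")
  }
  if (method == "spearman") {
    a <- rank(a); b <- rank(b)
    if (!is.null(confounds)) confounds <- apply(confounds, 2L, rank)
  }
  if (is.null(confounds) || ncol(confounds) == 0L)
    return(stats::cor(a, b))
  Z <- cbind(1, confounds)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("confound matrix is rank deficient")
  ra <- qr.resid(qz, a); rb <- qr.resid(qz, b)
  # a variable fully explained by the confounds has no residual variance
  # left to correlate; its partial correlation is 0
  if (stats::sd(ra) < 1e-10 * stats::sd(a) ||
      stats::sd(rb) < 1e-10 * stats::sd(b)) return(0)
  stats::cor(ra, rb)
}

# all permutations of 1..n as a matrix (n! rows); only used for small n
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Permutation p-value for a (partial) correlation
#'
#' Subject labels are shuffled for `a` only, preserving the links between `b`
#' and the confounds, and the partial correlation is recomputed per shuffle.
#' The p-value is two-sided on |rho|. For small samples (`factorial(n) <=
#' n_perm`, or `exact = TRUE`) the null is enumerated exhaustively and the
#' p-value is the exact tail fraction; otherwise `n_perm` random shuffles are
#' drawn and the add-one estimator `(1 + #{|rho_null| >= |rho_obs|}) /
#' (1 + n_perm)` is used.
#'
#' @inheritParams partial_correlation
#' @param n_perm number of random shuffles (default 10000, minimum 100).
#' @param seed integer seed for the shuffles.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exhaustive enumeration;
#'   `NULL` (default) enumerates automatically when feasible.
#' @return list with `rho`, `p`, `n_perm` (shuffles actually used), `exact`,
#'   `method`, `n`, `seed`.
#' @export
permutation_pvalue <- function(a, b, confounds = NULL,
                               method = c("pearson", "spearman"),
                               n_perm = 10000L, seed = 1L, exact = NULL) {
  method <- match.arg(method)
  if (n_perm < 100L) stop("`n_perm` must be at least 100")
  a <- as.numeric(a); b <- as.numeric(b)
  n <- length(a)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("constant `a` or `b`: correlation undefined")
  rho_obs <- partial_correlation(a, b, confounds, method)
  tol <- 1e-12
  if (is.null(exact)) exact <- factorial(n) <= n_perm
  if (exact) {
    perms <- .all_perms(n)
    rho_null <- apply(perms, 1L, function(ix)
      partial_correlation(a[ix], b, confounds, method))
    p <- mean(abs(rho_null) >= abs(rho_obs) - tol)
    used <- nrow(perms)
  } else {
    set.seed(seed)
    hits <- 0L
    for (r in seq_len(n_perm)) {
      rho_null <- partial_correlation(a[sample.int(n)], b, confounds, method)
      if (abs(rho_null) >= abs(rho_obs) - tol) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    used <- n_perm
  }
  list(rho = rho_obs, p = p, n_perm = used, exact = exact,
       method = method, n = n, seed = seed)
}

#' Hedges' g standardized mean difference with 95% CI
#'
#' `g = J (mean1 - mean2) / s_pooled` with the small-sample correction
#' `J = 1 - 3 / (4(n1 + n2) - 9)`; the CI uses the large-sample variance
#' `(n1 + n2)/(n1 n2) + g^2 / (2(n1 + n2 - 2))`.
#'
#' @param group1,group2 numeric vectors (each length >= 2).
#' @return list with `g`, `ci_low`, `ci_high`, `n1`, `n2`, `correction_j`.
#' @export
hedges_g <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 observations")
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("pooled SD is zero; effect size undefined")
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  g <- j * (mean(group1) - mean(group2)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2 - 2)))
  list(g = g, ci_low = g - 1.96 * se, ci_high = g + 1.96 * se,
       n1 = n1, n2 = n2, correction_j = j)
}

#' Bonferroni adjustment of a nominal p-value
#'
#' `p_adj = min(1, p * n_comparisons)`; the adjustment rule used by
#' [group_ttests_bonferroni()].
#'
#' @param p nominal (raw) p-value(s).
#' @param n_comparisons number of comparisons.
#' @return adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, n_comparisons) pmin(1, p * n_comparisons)

#' Patient-vs-control t-tests per diagnosis, Bonferroni corrected
#'
#' Pooled-variance (Student) two-tailed t-test of each diagnosis's patients
#' against their own matched controls, with Bonferroni adjustment
#' `p_adj = min(1, p * n_comparisons)`, plus Hedges' g per diagnosis.
#'
#' @param patients named list of numeric vectors (predicted WMA per patient),
#'   one element per diagnosis.
#' @param controls named list matching `patients` (matched control groups).
#' @param n_comparisons Bonferroni multiplier (default: number of diagnoses).
#' @return data.frame, one row per diagnosis: `diagnosis`, `n_patients`,
#'   `n_controls`, `t`, `df`, `p`, `p_adjusted`, `hedges_g`, `g_ci_low`,
#'   `g_ci_high`.
#' @export
group_ttests_bonferroni <- function(patients, controls,
                                    n_comparisons = length(patients)) {
  if (!identical(names(patients), names(controls)))
    stop("`patients` and `controls` must share diagnosis names and order")
  rows <- lapply(names(patients), function(d) {
    x <- patients[[d]]; y <- controls[[d]]
    if (length(x) < 2L || length(y) < 2L)
      stop("group sizes must be >= 2 (diagnosis ", d, ")")
    tt <- stats::t.test(x, y, var.equal = TRUE)
    g <- hedges_g(x, y)
    data.frame(diagnosis = d, n_patients = length(x), n_controls = length(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               p_adjusted = bonferroni_adjust(tt$p.value, n_comparisons),
               hedges_g = g$g, g_ci_low = g$ci_low, g_ci_high = g$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-way ANOVA across diagnoses with Holm post-hoc tests
#'
#' Classical one-way F-test of predicted-WMA Z-scores on diagnosis, preceded
#' by a (non-gating) Bartlett homoscedasticity report, followed by Holm
#' step-down adjusted pairwise pooled-SD t-tests.
#'
#' @param z numeric vector (e.g. per-patient predicted-WMA Z-scores).
#' @param labels group labels, same length as `z` (>= 2 groups, each >= 2).
#' @return list with `f`, `df1`, `df2`, `p`, `bartlett` (statistic, df, p),
#'   `pairwise` (data.frame: group1, group2, p_raw, p_holm).
#' @export
anova_oneway_holm <- function(z, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 groups")
  if (any(table(labels) < 2L)) stop("every group needs at least 2 observations")
  aovf <- stats::oneway.test(z ~ labels, var.equal = TRUE)
  bart <- stats::bartlett.test(z, labels)
  pw <- stats::pairwise.t.test(z, labels, p.adjust.method = "none",
                               pool.sd = TRUE)
  raw <- pw$p.value
  pairs <- which(!is.na(raw), arr.ind = TRUE)
  tab <- data.frame(group1 = rownames(raw)[pairs[, 1L]],
                    group2 = colnames(raw)[pairs[, 2L]],
                    p_raw = raw[pairs], stringsAsFactors = FALSE)
  tab$p_holm <- stats::p.adjust(tab$p_raw, method = "holm")
  list(f = unname(aovf$statistic), df1 = unname(aovf$parameter[1L]),
       df2 = unname(aovf$parameter[2L]), p = aovf$p.value,
       bartlett = list(statistic = unname(bart$statistic),
                       df = unname(bart$parameter), p = bart$p.value),
       pairwise = tab)
}

#' Containment of effect sizes in meta-analytic confidence intervals
#'
#' Checks, per diagnosis, whether an estimated effect size falls inside a
#' supplied (closed) meta-analytic interval.
#'
#' @param g_estimates named numeric vector of effect sizes.
#' @param meta_intervals named list (same names) of `c(low, high)` intervals.
#' @return data.frame with `diagnosis`, `g`, `low`, `high`, `contained`.
#' @export
ci_containment <- function(g_estimates, meta_intervals) {
  if (!all(names(g_estimates) %in% names(meta_intervals)))
    stop("every estimate needs a matching interval")
  rows <- lapply(names(g_estimates), function(d) {
    iv <- meta_intervals[[d]]
    if (length(iv) != 2L || iv[1L] > iv[2L])
      stop("inverted or malformed interval for ", d)
    data.frame(diagnosis = d, g = unname(g_estimates[[d]]),
               low = iv[1L], high = iv[2L],
               contained = iv[1L] <= g_estimates[[d]] & g_estimates[[d]] <= iv[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare two dependent (partial) correlations by subject bootstrap
#'
#' Both correlations share variable `a` (e.g. model predictions) and are
#' computed on the same subjects against `b1` and `b2` (e.g. 2-back and
#' 0-back scores), partialing out the same confounds. Subjects are resampled
#' with replacement; the p-value is the (two-sided) bootstrap percentile of 0
#' in the distribution of the difference `rho1 - rho2`.
#'
#' @inheritParams partial_correlation
#' @param b1,b2 the two outcome variables.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return list with `rho1`, `rho2`, `diff`, `p`, `n_boot`, `seed`.
#' @export
compare_dependent_correlations <- function(a, b1, b2, confounds = NULL,
                                           method = c("spearman", "pearson"),
                                           n_boot = 2000L, seed = 1L) {
  method <- match.arg(method)
  n <- length(a)
  if (length(b1) != n || length(b2) != n)
    stop("`a`, `b1`, `b2` must cover the same subjects")
  rho1 <- partial_correlation(a, b1, confounds, method)
  rho2 <- partial_correlation(a, b2, confounds, method)
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(r) {
    ix <- sample.int(n, replace = TRUE)
    cf <- if (is.null(confounds)) NULL else as.matrix(confounds)[ix, , drop = FALSE]
    d1 <- a[ix]
    if (stats::sd(d1) == 0 || stats::sd(b1[ix]) == 0 || stats::sd(b2[ix]) == 0)
      return(NA_real_)
    partial_correlation(d1, b1[ix], cf, method) -
      partial_correlation(d1, b2[ix], cf, method)
  }, numeric(1))
  diffs <- diffs[is.finite(diffs)]
  p <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  list(rho1 = rho1, rho2 = rho2, diff = rho1 - rho2, p = p,
       n_boot = n_boot, seed = seed)
}
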