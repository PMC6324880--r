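#' Signal-detection sensitivity (d-prime) from trial counts
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`. Extreme rates (0 or 1)
#' are handled with the log-linear 1/(2N) correction: rates are clipped to
#' `[1/(2N), 1 - 1/(2N)]` where N is the number of target (respectively
#' non-target) trials, keeping d' finite.
#'
#' @param hits,misses counts on target trials.
#' @param false_alarms,correct_rejections counts on non-target trials.
#' @return d-prime (numeric, vectorized over inputs).
#' @examples
#' dprime(hits = 21, misses = 4, false_alarms = 8, correct_rejections = 42)
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  n_t <- hits + misses
  n_n <- false_alarms + correct_rejections
  if (any(n_t < 1L) || any(n_n < 1L))
    stop("need at least one target and one non-target trial")
  hr <- pmin(pmax(hits / n_t, 1 / (2 * n_t)), 1 - 1 / (2 * n_t))
  far <- pmin(pmax(false_alarms / n_n, 1 / (2 * n_n)), 1 - 1 / (2 * n_n))
  stats::qnorm(hr) - stats::qnorm(far)
}

#' Centered moving average with shrinking edges
#'
#' Smooths a per-session score trace with an odd, centered window. At the
#' boundaries the window shrinks symmetrically to the available neighbours, so
#' the output has the same length as the input and constant or linear inputs
#' pass through unchanged in the interior.
#'
#' @param y numeric vector.
#' @param window odd window length, `<= length(y)` (default 5).
#' @return smoothed numeric vector, same length as `y`.
#' @export
moving_average <- function(y, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be a positive odd integer")
  if (window > length(y)) stop("`window` exceeds the series length")
  h <- window %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    r <- min(h, i - 1L, n - i)  # symmetric shrink at edges
    mean(y[(i - r):(i + r)])
  }, numeric(1))
}

#' Fit the inverse learning curve y = a - b/x
#'
#' The learning plateau `a` and learning-speed parameter `b` are obtained by
#' exact least squares: the model is linear in 1/x, so the fit is an ordinary
#' regression of y on 1/x with `a` the intercept and `b` minus the slope. The
#' plateau `a` is the modelled asymptotic d-prime and serves as the working
#' memory ability (WMA) summary.
#'
#' @param y per-session scores (d-prime), typically after [moving_average()].
#' @param x session indices (default `1:length(y)`); must not be constant.
#' @return object of class `plateau_fit`: list with `a`, `b`, `sse`, `fitted`.
#' @examples
#' x <- 1:25
#' fit_inverse_curve(3 - 2 / x)   # recovers a = 3, b = 2
#' @export
fit_inverse_curve <- function(y, x = seq_along(y)) {
  if (length(y) < 3L) stop("need at least 3 sessions to fit the inverse curve")
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (any(x < 1)) stop("session indices must be >= 1")
  if (stats::var(x) == 0) stop("session indices are degenerate (all equal)")
  z <- 1 / x
  fit <- stats::lm.fit(cbind(1, z), y)
  a <- unname(fit$coefficients[1L])
  b <- -unname(fit$coefficients[2L])
  structure(list(a = a, b = b, sse = sum(fit$residuals^2),
                 fitted = a - b / x, x = x, y = y),
            class = "plateau_fit")
}

#' @export
print.plateau_fit <- function(x, ...) {
  cat(sprintf("inverse learning curve: plateau a = %.4f, speed b = %.4f, sse = %.4g (%d sessions)\n",
              x$a, x$b, x$sse, length(x$y)))
  invisible(x)
}

#' Working memory ability from a session-wise d-prime trace
#'
#' Convenience wrapper chaining the five-session moving average and the
#' inverse-curve fit; returns the full fit whose `a` is the WMA estimate.
#'
#' @param dprimes per-session d-prime values.
#' @param window moving-average window (default 5).
#' @return a `plateau_fit` (see [fit_inverse_curve()]).
#' @export
wma_from_sessions <- function(dprimes, window = 5L) {
  fit_inverse_curve(moving_average(dprimes, window))
}
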