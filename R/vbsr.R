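#' Sparse Bayesian (ARD) linear regression of WMA on FC features
#'
#' Fits a linear model `y = intercept + X w + e` with automatic relevance
#' determination: each weight has a zero-mean Gaussian prior with its own
#' precision, and precisions are optimised by variational/EM updates of the
#' marginal likelihood. Irrelevant features see their precision diverge and
#' are pruned, yielding an automatically selected sparse set of connections.
#' Features and target are z-scored internally; the returned weights and
#' intercept are on the original scales.
#'
#' Updates per iteration (active features only): posterior
#' `Sigma = (beta X'X + diag(alpha))^-1`, `mu = beta Sigma X'y`; then
#' `alpha_j = (1 + 2 a0) / (mu_j^2 + Sigma_jj + 2 b0)` and
#' `beta = (n + 2 c0) / (|y - X mu|^2 + tr(X Sigma X') + 2 d0)`. With the
#' default flat hyperpriors these are exact EM steps on the log marginal
#' likelihood, which therefore increases monotonically; the trace is stored in
#' `free_energy`.
#'
#' @param X numeric matrix, subjects x features (e.g. 171 FC values).
#' @param y numeric response (learning plateaus), length `nrow(X)`.
#' @param hyper list of hyperparameters: Gamma hyperprior shapes/rates
#'   `a0`, `b0` (weight precisions) and `c0`, `d0` (noise precision), all 0 by
#'   default (flat); `prune` precision threshold (default 1e8) above which a
#'   feature is removed; `beta_max` cap on the noise precision (default 1e12)
#'   keeping noiseless problems numerically stable.
#' @param max_iter maximum update iterations (default 5000).
#' @param tol relative free-energy change declaring convergence (default 1e-8).
#' @param seed optional integer recorded in the model (the fit itself is
#'   deterministic: initialization is all precisions equal).
#' @return object of class `wma_model`: list with `weights` (original scale,
#'   zeros off-support), `intercept`, `support` (indices), `support_labels`,
#'   `ard_precisions`, standardization parameters, `converged`, `iterations`,
#'   `free_energy` (trace), `sigma2` (residual variance, original scale).
#' @seealso [predict.wma_model()], [loocv()], [contribution_ratios()]
#' @export
fit_vbsr <- function(X, y, hyper = list(), max_iter = 5000L, tol = 1e-8,
                     seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("`y` length must equal nrow(X)")
  if (n < 3L) stop("need at least 3 subjects")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  hp <- utils::modifyList(list(a0 = 0, b0 = 0, c0 = 0, d0 = 0,
                               prune = 1e8, beta_max = 1e12,
                               beta_growth = 2), hyper)
  labels <- colnames(X)
  if (is.null(labels)) labels <- sprintf("feature_%03d", seq_len(p))

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2L, stats::sd)
  usable <- x_sd > 0
  if (!all(usable))
    warning(sum(!usable), " zero-variance feature(s) dropped from the fit")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)

  empty_model <- function(converged = TRUE, iters = 0L, fe = numeric(0)) {
    structure(list(weights = stats::setNames(numeric(p), labels),
                   intercept = y_mean, support = integer(0),
                   support_labels = character(0),
                   ard_precisions = stats::setNames(rep(Inf, p), labels),
                   x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
                   converged = converged, iterations = iters,
                   free_energy = fe, sigma2 = stats::var(y), hyper = hp,
                   seed = seed, n_train = n),
              class = "wma_model")
  }
  if (y_sd == 0 || !any(usable)) return(empty_model())

  Xs <- scale(X[, usable, drop = FALSE])
  ys <- (y - y_mean) / y_sd
  pa <- ncol(Xs)
  active <- seq_len(pa)
  alpha <- rep(1, pa)
  beta <- 10                      # ~10% residual variance on the z-scale
  yy <- sum(ys^2)

  fe_trace <- numeric(0)
  mu <- numeric(pa)
  sig_diag <- numeric(pa)
  iter <- 0L
  converged <- FALSE
  prev_fe <- -Inf

  while (iter < max_iter) {
    iter <- iter + 1L
    Xa <- Xs[, active, drop = FALSE]
    ka <- length(active)
    Xty <- crossprod(Xa, ys)
    if (ka <= n) {
      XtX <- crossprod(Xa)
      M <- beta * XtX + diag(alpha[active], ka)
      Sig <- chol2inv(chol(M))
      mu_a <- as.numeric(beta * Sig %*% Xty)
      sd_a <- diag(Sig)
      trXSX <- sum(XtX * Sig)
      logdet_Minv <- -2 * sum(log(diag(chol(M))))
    } else {
      Ainv <- 1 / alpha[active]
      XAi <- sweep(Xa, 2L, Ainv, `*`)          # n x ka: X * Ainv per column
      C0 <- XAi %*% t(Xa)                       # X A^-1 X'
      B <- C0 + diag(1 / beta, n)
      cB <- chol(B)
      BiX <- backsolve(cB, forwardsolve(t(cB), Xa))
      sd_a <- Ainv - Ainv^2 * colSums(Xa * BiX)
      mu_a <- beta * (Ainv * as.numeric(Xty) -
                        Ainv * as.numeric(crossprod(Xa, backsolve(cB, forwardsolve(t(cB), C0 %*% ys)))))
      BiC0 <- backsolve(cB, forwardsolve(t(cB), C0))
      trXSX <- sum(diag(C0)) - sum(BiC0 * t(C0))
      # log|Sigma^{-1}| = log|B| + sum(log alpha) + n log beta
      logdet_Minv <- -(2 * sum(log(diag(cB))) + sum(log(alpha[active])) + n * log(beta))
    }
    resid <- ys - as.numeric(Xa %*% mu_a)
    sse <- sum(resid^2)

    # log marginal likelihood at current (alpha, beta)
    quad <- beta * (yy - sum(Xty * mu_a))
    logdetC <- -logdet_Minv - sum(log(alpha[active])) - n * log(beta)
    fe <- -0.5 * (n * log(2 * pi) + logdetC + quad)
    fe_trace <- c(fe_trace, fe)

    alpha_new <- (1 + 2 * hp$a0) / (mu_a^2 + sd_a + 2 * hp$b0)
    # damped (generalized-EM) noise-precision step: moving part-way toward
    # the EM optimum keeps the evidence non-decreasing while preventing an
    # early interpolating local optimum on near-noiseless data
    beta_new <- min((n + 2 * hp$c0) / (sse + trXSX + 2 * hp$d0),
                    hp$beta_growth * beta, hp$beta_max)

    keep <- alpha_new <= hp$prune
    alpha[active] <- alpha_new
    mu <- numeric(pa); mu[active] <- mu_a
    sig_diag <- numeric(pa); sig_diag[active] <- sd_a
    pruned_now <- !all(keep)
    active <- active[keep]
    beta <- beta_new

    if (length(active) == 0L) { converged <- TRUE; break }
    if (!pruned_now && is.finite(prev_fe) &&
        abs(fe - prev_fe) < tol * max(1, abs(fe))) { converged <- TRUE; break }
    prev_fe <- fe
  }

  w_std <- numeric(pa)
  w_std[active] <- mu[active]
  weights <- stats::setNames(numeric(p), labels)
  weights[usable] <- w_std * y_sd / x_sd[usable]
  support <- unname(which(weights != 0))
  precisions <- stats::setNames(rep(Inf, p), labels)
  precisions[usable] <- alpha

  intercept <- y_mean - sum(weights * x_mean)
  sigma2 <- (1 / beta) * y_sd^2

  structure(list(weights = weights, intercept = intercept,
                 support = support, support_labels = labels[support],
                 ard_precisions = precisions,
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
                 converged = converged, iterations = iter,
                 free_energy = fe_trace, sigma2 = sigma2, hyper = hp,
                 seed = seed, n_train = n),
            class = "wma_model")
}

#' @export
print.wma_model <- function(x, ...) {
  cat(sprintf("wma_model: %d/%d connections selected, intercept %.4f (%s after %d iterations)\n",
              length(x$support), length(x$weights), x$intercept,
              if (x$converged) "converged" else "not converged", x$iterations))
  if (length(x$support)) {
    w <- x$weights[x$support]
    for (i in order(-abs(w)))
      cat(sprintf("  %-55s % .5f\n", names(w)[i], w[i]))
  }
  invisible(x)
}

#' Predict working memory ability from FC
#'
#' `prediction = intercept + sum_i w_i x_i` on the original feature scale.
#'
#' @param object a `wma_model`.
#' @param newdata FC vector (length matching the model) or subjects x features
#'   matrix.
#' @param ... unused.
#' @return numeric vector of predicted WMA, one value per subject.
#' @export
predict.wma_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$weights))
    stop(sprintf("FC has %d features; model expects %d",
                 ncol(newdata), length(object$weights)))
  as.numeric(newdata %*% object$weights) + object$intercept
}

#' Leave-one-out cross-validated prediction accuracy
#'
#' Each subject is predicted by a model trained on all other subjects;
#' accuracy is `R^2 = 1 - SSE/SST` over the held-out predictions (negative
#' when predictions do worse than the mean).
#'
#' @inheritParams fit_vbsr
#' @return list with `r2`, `predictions` (held-out, per subject) and `y`.
#' @export
loocv <- function(X, y, hyper = list(), max_iter = 5000L, tol = 1e-8) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 4L) stop("leave-one-out cross-validation needs at least 4 subjects")
  preds <- vapply(seq_len(n), function(i) {
    m <- fit_vbsr(X[-i, , drop = FALSE], y[-i], hyper = hyper,
                  max_iter = max_iter, tol = tol)
    predict(m, X[i, ])
  }, numeric(1))
  sse <- sum((y - preds)^2)
  sst <- sum((y - mean(y))^2)
  list(r2 = 1 - sse / sst, predictions = preds, y = y)
}

#' Per-connection contribution ratios of a fitted model
#'
#' Contribution of selected connection `i` is the training-set mean of its
#' weighted FC, `mean(w_i x_i)`, expressed as a signed percentage of the sum
#' over all selected connections. Percentages sum to 100 up to rounding and
#' may be individually negative.
#'
#' @param model a fitted `wma_model`.
#' @param X_train the training FC matrix the model was fitted on.
#' @return data.frame with `label`, `weight`, `mean_weighted_fc`,
#'   `contribution_pct`, ordered by decreasing |contribution|.
#' @export
contribution_ratios <- function(model, X_train) {
  stopifnot(inherits(model, "wma_model"))
  X_train <- as.matrix(X_train)
  if (ncol(X_train) != length(model$weights))
    stop("X_train feature count does not match the model")
  if (length(model$support) == 0L) stop("model has an empty support")
  idx <- model$support
  mwfc <- colMeans(X_train[, idx, drop = FALSE]) * model$weights[idx]
  denom <- sum(mwfc)
  if (abs(denom) < 1e-12)
    stop("total mean weighted FC is zero; contribution ratios undefined")
  out <- data.frame(label = model$support_labels,
                    weight = unname(model$weights[idx]),
                    mean_weighted_fc = unname(mwfc),
                    contribution_pct = unname(100 * mwfc / denom),
                    stringsAsFactors = FALSE)
  out[order(-abs(out$contribution_pct)), ]
}
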