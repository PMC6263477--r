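#' Fit a time-varying autoregressive model by recursive least squares
#'
#' Models a filtered, normalized respiratory sound `x` as a time-varying
#' autoregression
#' \deqn{x[n] = -\sum_{k=1}^{M} a_k[n]\, x[n-k] + v[n],}
#' estimating one coefficient vector per sample with exponentially weighted
#' recursive least squares. The forgetting factor `lambda` sets the
#' estimator's memory (effective window about `1 / (1 - lambda)` samples);
#' values close to 1 track slow spectral drift while letting transient events
#' such as crackles show up as abrupt coefficient changes. Defaults (`order =
#' 4`, `lambda = 0.97`) are the values used by the crackle detector.
#'
#' The recursion starts once `order` past samples exist; the first `order`
#' rows of the trajectory hold the zero initial value. The inverse
#' correlation state is initialized to `diag(1/delta)` and re-symmetrized
#' each step.
#'
#' @param x Numeric signal (a normalized-stage [sound_recording()] or bare
#'   numeric vector), longer than `order`.
#' @param order Model order M (default 4).
#' @param lambda Forgetting factor in (0, 1]; `lambda = 1` gives the
#'   time-invariant (growing-window) least-squares fit.
#' @param delta Initialization scale for the inverse correlation matrix
#'   (default 0.01).
#' @return An object of class `tvar_rls` with components `coeffs` (n x M
#'   matrix, row n = \eqn{a_k[n]}, the fixed \eqn{a_0 = 1} is not stored),
#'   `errors` (a-priori prediction errors, 0 for the first `order` samples),
#'   `order`, `lambda`, `delta`, `n`.
#' @examples
#' set.seed(1)
#' x <- as.numeric(stats::filter(rnorm(5000), c(0.5, -0.3), "recursive"))
#' fit <- tvar_rls(peak_normalize(x), order = 2, lambda = 1)
#' coef(fit)  # close to -(0.5, -0.3)
#' @export
tvar_rls <- function(x, order = 4L, lambda = 0.97, delta = 0.01) {
  samples <- if (inherits(x, "sound_recording")) x$samples else as.numeric(x)
  if (!all(is.finite(samples))) stop("signal contains non-finite values")
  if (length(samples) <= order) {
    stop("signal must be longer than the model order")
  }
  res <- .rls_tvar(samples, as.integer(order), lambda, delta)
  colnames(res$coeffs) <- paste0("a", seq_len(order))
  structure(
    list(coeffs = res$coeffs, errors = res$errors,
         order = as.integer(order), lambda = lambda, delta = delta,
         n = length(samples)),
    class = "tvar_rls"
  )
}

#' @export
print.tvar_rls <- function(x, ...) {
  cat(sprintf("TVAR(%d) model estimated by RLS (lambda = %g) over %d samples\n",
              x$order, x$lambda, x$n))
  cat("Final coefficients:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
#' @describeIn tvar_rls Final coefficient vector \eqn{a_k[n]} at the last sample.
coef.tvar_rls <- function(object, ...) {
  object$coeffs[object$n, ]
}

#' @export
#' @describeIn tvar_rls A-priori prediction errors \eqn{e[n]}.
residuals.tvar_rls <- function(object, ...) {
  object$errors
}

#' @export
summary.tvar_rls <- function(object, ...) {
  n <- object$n
  tail_rows <- max(object$order + 1L, floor(0.8 * n)):n
  out <- list(
    order = object$order, lambda = object$lambda, n = n,
    final = coef(object),
    tail_mean = colMeans(object$coeffs[tail_rows, , drop = FALSE]),
    rmse = sqrt(mean(object$errors[(object$order + 1L):n]^2))
  )
  class(out) <- "summary.tvar_rls"
  out
}

#' @export
print.summary.tvar_rls <- function(x, ...) {
  cat(sprintf("TVAR(%d), lambda = %g, %d samples\n", x$order, x$lambda, x$n))
  cat("Mean coefficients over final 20% of samples:\n")
  print(round(x$tail_mean, 4))
  cat(sprintf("Prediction RMSE: %.4g\n", x$rmse))
  invisible(x)
}

#' @export
plot.tvar_rls <- function(x, fs = NULL, ...) {
  idx <- seq_len(x$n)
  xv <- if (is.null(fs)) idx else (idx - 1) / fs
  xl <- if (is.null(fs)) "sample" else "time (s)"
  old <- graphics::par(mfrow = c(x$order, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (k in seq_len(x$order)) {
    graphics::plot(xv, x$coeffs[, k], type = "l", xlab = xl,
                   ylab = bquote(a[.(k)]), ...)
  }
  invisible(x)
}

#' Export a TVAR coefficient trajectory as CSV
#'
#' Columns: `sample_index`, `a1..aM`, `e` (a-priori error).
#'
#' @param fit A [tvar_rls()] fit.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(fit, path) {
  stopifnot(inherits(fit, "tvar_rls"))
  df <- data.frame(sample_index = seq_len(fit$n), fit$coeffs, e = fit$errors)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Batch (time-invariant) least-squares AR fit
#'
#' Solves the normal equations of the covariance-method AR problem exactly:
#' with regressors \eqn{u[n] = (-x[n-1], ..., -x[n-M])} over
#' \eqn{n = M+1..N}, returns \eqn{\hat a = (U'U)^{-1} U' x}. Serves as the
#' time-invariant reference the RLS estimator must agree with at
#' `lambda = 1` (up to the `delta` regularization of the recursive form).
#'
#' @param x Numeric signal, much longer than `order`.
#' @param order AR model order.
#' @return Coefficient vector `a1..aM` in the sign convention of [tvar_rls()].
#' @export
fit_ar_batch <- function(x, order = 4L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= 2L * order) stop("signal too short for the requested order")
  U <- sapply(seq_len(order), function(k) -x[(order + 1L - k):(n - k)])
  y <- x[(order + 1L):n]
  G <- crossprod(U)
  if (rcond(G) < 1e-12) {
    stop("rank-deficient normal equations (constant or degenerate signal)")
  }
  a <- solve(G, crossprod(U, y))
  stats::setNames(drop(a), paste0("a", seq_len(order)))
}
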