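#' No-intercept least squares
#'
#' Minimizes `||y - X b||^2` over `b` with no intercept column, via the QR
#' decomposition ([stats::lm.fit()]). Conventions used throughout the
#' package: `r` is the Pearson correlation between observed and fitted
#' values; the residual SD uses an `n - p` denominator; coefficient
#' standard errors come from `(X'X)^-1 * sd^2`.
#'
#' @param X numeric matrix (or vector, taken as one column) of predictors;
#'   must have full column rank and at least as many rows as columns.
#' @param y numeric response, same length as `nrow(X)`.
#' @return An object of class `"lstsq_fit"`: list with `coefficients`,
#'   `se`, `fitted`, `residuals`, `r`, `sd`, `n`, `p`.
#' @examples
#' x <- 1:5
#' lstsq_no_intercept(x, 2 * x)$coefficients  # exactly 2
#' @export
lstsq_no_intercept <- function(X, y) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  X <- as.matrix(X)
  if (!is.numeric(X) || !is.numeric(y)) {
    stop_validation("`X` and `y` must be numeric")
  }
  if (nrow(X) != length(y)) stop_validation("`X` and `y` sizes differ")
  if (nrow(X) < ncol(X)) {
    stop_validation("need at least as many observations as predictors")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    stop_validation("predictor matrix is rank deficient (collinear columns)")
  }
  n <- nrow(X)
  p <- ncol(X)
  fitted <- as.numeric(X %*% fit$coefficients)
  res <- y - fitted
  rss <- sum(res^2)
  sd <- if (n > p) sqrt(rss / (n - p)) else NA_real_
  r <- if (n >= 2 && stats::sd(fitted) > 0 && stats::sd(y) > 0) {
    stats::cor(y, fitted)
  } else {
    NA_real_
  }
  se <- if (!is.na(sd)) sqrt(diag(solve(crossprod(X))) * sd^2) else
    rep(NA_real_, p)
  names(se) <- colnames(X)
  structure(
    list(coefficients = fit$coefficients, se = se, fitted = fitted,
         residuals = res, r = r, sd = sd, n = n, p = p),
    class = "lstsq_fit"
  )
}

#' @export
print.lstsq_fit <- function(x, ...) {
  cat(sprintf("No-intercept least squares (n = %d, p = %d)\n", x$n, x$p))
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(tab)
  cat(sprintf("r = %.4f, residual SD = %.4g\n", x$r, x$sd))
  invisible(x)
}

#' Mean-of-ratios estimator
#'
#' For paired observations `(y_i, x_i)` with all `x_i > 0`, the mean and
#' sample SD (n - 1 denominator) of the per-pair ratios `y_i / x_i`. This
#' is the estimator behind "mean K = ... +/- ..." style constants reported
#' from per-point ratios.
#'
#' @param y numerator values.
#' @param x denominator values (> 0), same length.
#' @return List with `mean`, `sd` (NA for a single pair), `n`, `ratios`.
#' @export
ratio_mean_estimator <- function(y, x) {
  if (!is.numeric(y) || !is.numeric(x) || length(y) != length(x)) {
    stop_validation("`y` and `x` must be numeric vectors of equal length")
  }
  if (length(x) == 0L) stop_validation("need at least one pair")
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_domain("all `x` must be finite and > 0")
  }
  ratios <- y / x
  list(
    mean = mean(ratios),
    sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
    n = length(ratios),
    ratios = ratios
  )
}
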