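#' Local polynomial regression (LOESS) with tricube weights
#'
#' Fits a locally weighted polynomial regression of `y` on one or two
#' predictor columns, evaluated directly at every observation. For each
#' evaluation point the `ceiling(span * n)` nearest neighbours are selected
#' (absolute difference in 1D, Euclidean distance on scaled columns in 2D;
#' points tied with the furthest neighbour are included with weight 0),
#' weighted by the tricube kernel \eqn{w = (1 - (d/d_{max})^3)^3}, and a
#' polynomial of the requested degree is fitted by weighted least squares;
#' the fitted value is the local prediction at that point.
#'
#' This is the adjustment engine for polysome log-ratios: the residuals of a
#' `local_fit` of the light/heavy log-ratio on log2 ORF length are the
#' ORF-length-adjusted log-ratios (see [adjust_by_orf()]).
#'
#' Unlike [stats::loess()], which by default evaluates on an interpolation
#' surface over a kd-tree, every point here is fitted exactly; fitted values
#' can therefore differ from `stats::loess` at roughly the 1e-3 level unless
#' that function is run with `surface = "direct"`. Fitting is Gaussian
#' (least squares) with no robustness iterations, matching R's defaults
#' otherwise (`span = 0.75`, `degree = 2`).
#'
#' With two predictors, each column is scaled by its 10%-trimmed standard
#' deviation before distances are computed; a column with zero trimmed
#' spread is dropped with a warning, so a degenerate second predictor
#' reduces the fit to the 1D fit on the remaining column.
#'
#' @param x numeric vector or matrix of predictors (1 or 2 columns).
#' @param y numeric response vector.
#' @param span fraction of the data in each local neighbourhood, in (0, 1].
#' @param degree local polynomial degree, 1 or 2.
#'
#' @return An object of class `"local_fit"` with components `fitted`,
#'   `residuals` (`y - fitted`, exact), `r.squared`
#'   (\eqn{1 - SS_{res}/SS_{tot}}; defined as 1 when `y` is constant),
#'   `span`, `degree`, `q` (neighbourhood size) and the training data.
#'
#' @examples
#' set.seed(1)
#' x <- sort(runif(80, 0, 10))
#' y <- sin(x) + rnorm(80, sd = 0.1)
#' fit <- local_fit(x, y)
#' fit$r.squared
#' head(residuals(fit))
#' predict(fit, c(2.5, 7.5))
#' @export
local_fit <- function(x, y, span = 0.75, degree = 2) {
  xm <- as.matrix(x)
  if (!is.numeric(xm)) stop_input("predictors must be numeric")
  storage.mode(xm) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(xm) != n) stop_input("x has %d rows but y has length %d", nrow(xm), n)
  if (n < 3L) stop_input("need at least 3 observations, got %d", n)
  if (ncol(xm) < 1L || ncol(xm) > 2L)
    stop_input("x must have 1 or 2 columns, got %d", ncol(xm))
  if (anyNA(xm) || any(!is.finite(xm)) || anyNA(y) || any(!is.finite(y)))
    stop_input("non-finite values in x or y")
  if (!is.numeric(span) || length(span) != 1L || is.na(span) ||
      span <= 0 || span > 1)
    stop_config("'span' must be a single number in (0, 1]")
  if (!degree %in% c(1, 2)) stop_config("'degree' must be 1 or 2")
  degree <- as.integer(degree)

  # 2D: scale columns by 10%-trimmed sd; drop zero-spread columns
  keep <- seq_len(ncol(xm))
  scl <- rep(1, ncol(xm))
  if (ncol(xm) == 2L) {
    scl <- apply(xm, 2L, trimmed_sd)
    if (any(scl <= 0)) {
      keep <- which(scl > 0)
      warning(sprintf("dropping %d zero-spread predictor column(s)",
                      sum(scl <= 0)), call. = FALSE)
    }
  }
  xs <- xm[, keep, drop = FALSE]
  if (length(keep) == 2L) xs <- sweep(xs, 2L, scl[keep], "/")

  q <- as.integer(ceiling(span * n))
  if (q < degree + 2L)
    stop_config("span too small: window of %d points cannot support degree %d",
                q, degree)

  if (ncol(xs) == 0L) {
    fitted <- rep(mean(y), n)
    n_fallback <- n
  } else {
    res <- loess_eval_cpp(xs, y, xs, q, degree)
    fitted <- as.numeric(res$fitted)
    n_fallback <- res$n_fallback
  }
  if (n_fallback > 0L)
    warning(sprintf("%d of %d local fits were rank deficient; fell back to local weighted mean",
                    n_fallback, n), call. = FALSE)

  residual <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(residual^2) / ss_tot

  structure(list(
    x = xm, y = y, span = span, degree = degree, q = q,
    keep = keep, scale = scl,
    fitted = fitted, residuals = residual, r.squared = r2,
    n_fallback = n_fallback,
    call = match.call()
  ), class = "local_fit")
}

# sd of the central 90% of the values (5% trimmed from each tail);
# the distance normalisation used for two-predictor fits
trimmed_sd <- function(v) {
  n <- length(v)
  k <- floor(0.05 * n)
  sv <- sort(v)
  if (n - 2L * k < 2L) return(stats::sd(v))
  stats::sd(sv[(k + 1L):(n - k)])
}

#' Predict from a local regression fit
#'
#' Evaluates the same local fitting procedure at new predictor values.
#' Points at the training locations reproduce the training `fitted` values
#' exactly. Prediction outside the training range (per-column bounding box)
#' is refused by default, or clamped to the range with a warning.
#'
#' @param object a [local_fit()] object.
#' @param newdata numeric vector or matrix with the same number of predictor
#'   columns as the training data. Missing: returns the training fitted
#'   values.
#' @param extrapolation `"error"` (default) or `"clamp"`.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.local_fit <- function(object, newdata,
                              extrapolation = c("error", "clamp"), ...) {
  if (missing(newdata)) return(object$fitted)
  extrapolation <- match.arg(extrapolation)
  xe <- as.matrix(newdata)
  storage.mode(xe) <- "double"
  if (ncol(xe) == 1L && ncol(object$x) > 1L && nrow(xe) == ncol(object$x))
    xe <- matrix(as.numeric(xe), ncol = ncol(object$x))  # a bare row vector
  if (ncol(xe) != ncol(object$x))
    stop_input("newdata has %d columns; fit used %d", ncol(xe), ncol(object$x))
  if (anyNA(xe) || any(!is.finite(xe))) stop_input("non-finite values in newdata")

  lo <- apply(object$x, 2L, min)
  hi <- apply(object$x, 2L, max)
  out_of_range <- sweep(xe, 2L, lo, "<") | sweep(xe, 2L, hi, ">")
  if (any(out_of_range)) {
    if (extrapolation == "error")
      stop_input("%d prediction point(s) outside the training range; use extrapolation = \"clamp\" to clamp",
                 sum(rowSums(out_of_range) > 0))
    warning(sprintf("clamping %d prediction point(s) to the training range",
                    sum(rowSums(out_of_range) > 0)), call. = FALSE)
    for (k in seq_len(ncol(xe))) xe[, k] <- pmin(pmax(xe[, k], lo[k]), hi[k])
  }

  xs_train <- object$x[, object$keep, drop = FALSE]
  xs_new <- xe[, object$keep, drop = FALSE]
  if (length(object$keep) == 2L) {
    xs_train <- sweep(xs_train, 2L, object$scale[object$keep], "/")
    xs_new <- sweep(xs_new, 2L, object$scale[object$keep], "/")
  }
  if (ncol(xs_new) == 0L) return(rep(mean(object$y), nrow(xe)))
  res <- loess_eval_cpp(xs_train, object$y, xs_new, object$q, object$degree)
  as.numeric(res$fitted)
}

#' @export
fitted.local_fit <- function(object, ...) object$fitted

#' @export
residuals.local_fit <- function(object, ...) object$residuals

#' @export
print.local_fit <- function(x, ...) {
  cat("Local polynomial regression (tricube weights, direct evaluation)\n")
  cat(sprintf("  n = %d, predictors = %d, span = %g (q = %d), degree = %d\n",
              length(x$y), ncol(x$x), x$span, x$q, x$degree))
  cat(sprintf("  R-squared: %.4f\n", x$r.squared))
  invisible(x)
}

#' @export
summary.local_fit <- function(object, ...) {
  structure(list(
    n = length(object$y), p = ncol(object$x), span = object$span,
    q = object$q, degree = object$degree, r.squared = object$r.squared,
    residual_sd = stats::sd(object$residuals),
    residual_quartiles = stats::quantile(object$residuals,
                                         c(0, 0.25, 0.5, 0.75, 1)),
    n_fallback = object$n_fallback
  ), class = "summary.local_fit")
}

#' @export
print.summary.local_fit <- function(x, ...) {
  cat("Local polynomial regression\n")
  cat(sprintf("  n = %d, predictors = %d, span = %g (q = %d), degree = %d\n",
              x$n, x$p, x$span, x$q, x$degree))
  cat(sprintf("  R-squared = %.4f, residual sd = %.4f\n",
              x$r.squared, x$residual_sd))
  cat("  residual quartiles:\n")
  print(signif(x$residual_quartiles, 4))
  if (x$n_fallback > 0)
    cat(sprintf("  %d rank-deficient local fit(s) used the local weighted mean\n",
                x$n_fallback))
  invisible(x)
}

#' Plot a 1D local regression fit
#'
#' Scatter plot of the data with the fitted curve overlaid (first predictor
#' on the x axis).
#'
#' @param x a [local_fit()] object.
#' @param ... passed to [plot()].
#' @export
plot.local_fit <- function(x, ...) {
  ord <- order(x$x[, 1L])
  graphics::plot(x$x[, 1L], x$y, xlab = "x", ylab = "y",
                 col = "grey40", pch = 16, cex = 0.5, ...)
  graphics::lines(x$x[ord, 1L], x$fitted[ord], col = "red3", lwd = 2)
  invisible(x)
}

#' Serialize a local regression fit to TSV
#'
#' Writes one row per observation with the predictors, response, fitted
#' value and residual.
#'
#' @param fit a [local_fit()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_local_fit <- function(fit, path) {
  stopifnot(inherits(fit, "local_fit"))
  df <- as.data.frame(fit$x)
  names(df) <- paste0("x", seq_len(ncol(fit$x)))
  df$y <- fit$y
  df$fitted <- fit$fitted
  df$residual <- fit$residuals
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
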