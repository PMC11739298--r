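# Correlation machinery: Pearson, point-biserial, and the biserial
# transformation used when a dichotomy (fail/success) is assumed to reflect
# an underlying latent continuum.

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3, nonzero variance).
#' @return Object of class `correlation_result` with `kind = "pearson"`,
#'   `r`, `n`, `df`, `p`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop_user("`x` and `y` differ in length")
  n <- length(x)
  if (n < 3) stop_user("need n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop_user("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(kind = "pearson", r = unname(ct$estimate), n = n,
                 df = unname(ct$parameter), p = ct$p.value),
            class = "correlation_result")
}

#' Point-biserial correlation between a dichotomy and a continuous variable
#'
#' Pearson correlation of the continuous variable with a 0/1 coding of the
#' dichotomy, with the usual t-based two-sided p-value.
#'
#' @param x Continuous values.
#' @param success Logical (or 0/1) vector of the same length.
#' @return A `correlation_result` with `kind = "point_biserial"`, carrying
#'   `n_success` for the biserial transformation.
#' @export
point_biserial <- function(x, success) {
  success <- as.logical(success)
  if (length(x) != length(success)) stop_user("length mismatch")
  if (!any(success) || all(success)) {
    stop_user("dichotomy is degenerate (all failures or all successes)")
  }
  res <- pearson_corr(x, as.numeric(success))
  res$kind <- "point_biserial"
  res$n_success <- sum(success)
  res
}

#' Biserial correlation from a point-biserial coefficient
#'
#' Rescales a point-biserial correlation to the biserial coefficient under
#' the assumption that the dichotomy cuts an underlying standard-normal
#' continuum: `r_b = r_pb * sqrt(p * q) / y`, where `p` is the success
#' proportion, `q = 1 - p`, and `y` is the standard-normal density at the
#' `p` quantile. The p-value of the underlying point-biserial t-test is
#' carried through unchanged.
#'
#' @param r_pb Point-biserial correlation, or a `correlation_result` from
#'   [point_biserial()].
#' @param n Total sample size (ignored when `r_pb` is a result object).
#' @param n_success Number of successes, strictly between 0 and `n`.
#' @return A `correlation_result` with `kind = "biserial"`: `r` (the
#'   biserial coefficient), `r_pb`, `p_success`, `ordinate`, `n`, `p`.
#' @export
#' @examples
#' biserial_from_point_biserial(0.653, n = 8, n_success = 4)  # r_b = 0.819
biserial_from_point_biserial <- function(r_pb, n = NULL, n_success = NULL) {
  p_carry <- NA_real_
  if (inherits(r_pb, "correlation_result")) {
    n <- r_pb$n
    n_success <- n_success %||% r_pb$n_success
    p_carry <- r_pb$p
    r_pb <- r_pb$r
  }
  if (is.null(n) || is.null(n_success)) stop_user("`n` and `n_success` required")
  if (abs(r_pb) > 1) stop_user("|r_pb| must be <= 1")
  if (n_success <= 0 || n_success >= n) {
    stop_user("`n_success` must be strictly between 0 and n (ordinate undefined)")
  }
  ps <- n_success / n
  z <- stats::qnorm(ps)
  y <- stats::dnorm(z)
  rb <- r_pb * sqrt(ps * (1 - ps)) / y
  if (is.na(p_carry) && n >= 3 && abs(r_pb) < 1) {
    tt <- r_pb * sqrt((n - 2) / (1 - r_pb^2))
    p_carry <- 2 * stats::pt(-abs(tt), n - 2)
  }
  structure(list(kind = "biserial", r = rb, r_pb = r_pb, p_success = ps,
                 ordinate = y, n = n, df = n - 2, p = p_carry),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  switch(x$kind,
    pearson = cat(sprintf("Pearson r(%d) = %.3f, p = %.4g\n", x$df, x$r, x$p)),
    point_biserial = cat(sprintf("Point-biserial r_pb(%d) = %.3f, p = %.4g\n",
                                 x$df, x$r, x$p)),
    biserial = cat(sprintf(
      "Biserial r_b = %.3f (from r_pb(%d) = %.3f, success %d/%d), p = %.4g\n",
      x$r, x$df, x$r_pb, round(x$p_success * x$n), x$n, x$p))
  )
  invisible(x)
}
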