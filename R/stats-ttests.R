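# t-tests, effect sizes and the hourly FDR-corrected test series, computable
# both from raw values and from printed summary statistics (n, M, SD).

#' Group summary statistics
#'
#' @param n Group size (>= 2).
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) stop_user("group size must be >= 2")
  if (sd < 0) stop_user("standard deviation must be >= 0")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) return(g)
  g <- as.numeric(g)
  if (length(g) < 2) stop_user("need >= 2 observations per group")
  group_summary(length(g), mean(g), stats::sd(g))
}

#' Independent two-sample t-test (Student or Welch)
#'
#' Computes the two-sided independent-samples t-test from raw values or
#' from summary statistics. `variant = "auto"` (raw data only) picks Welch
#' when Levene's test (centre = mean) rejects homogeneity at alpha = 0.05
#' and Student otherwise; both variants can be forced and are then available
#' from `(n, M, SD)` alone. Cohen's d uses the unweighted-variance
#' denominator (see [cohens_d_independent()]).
#'
#' @param g1,g2 Numeric vectors of raw values, or [group_summary()] objects.
#' @param variant `"auto"`, `"student"` or `"welch"`.
#' @param conf_level Confidence level of the mean-difference interval.
#' @return Object of class `t_test_result`: list with `t`, `df`, `p`, `d`,
#'   `ci95`, `variant`, `mean_diff` and the two group summaries.
#' @export
#' @examples
#' independent_t(group_summary(17, 42.65, 14.99),
#'               group_summary(18, 79.63, 28.18), variant = "welch")
independent_t <- function(g1, g2, variant = c("auto", "student", "welch"),
                          conf_level = 0.95) {
  variant <- match.arg(variant)
  raw <- is.numeric(g1) && is.numeric(g2)
  s1 <- as_group_summary(g1); s2 <- as_group_summary(g2)
  if (s1$sd == 0 && s2$sd == 0) stop_user("zero variance in both groups")
  if (variant == "auto") {
    if (!raw) stop_user("`variant = \"auto\"` needs raw values (Levene's test)")
    lev <- levene_test(list(g1, g2))
    variant <- if (lev$p < 0.05) "welch" else "student"
  }
  diff <- s1$mean - s2$mean
  if (variant == "student") {
    sp2 <- ((s1$n - 1) * s1$sd^2 + (s2$n - 1) * s2$sd^2) / (s1$n + s2$n - 2)
    se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
    df <- s1$n + s2$n - 2
  } else {
    v1 <- s1$sd^2 / s1$n; v2 <- s2$sd^2 / s2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (s1$n - 1) + v2^2 / (s2$n - 1))
  }
  t <- diff / se
  p <- 2 * stats::pt(-abs(t), df)
  tc <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(t = t, df = df, p = p,
                 d = cohens_d_independent(s1, s2, signed = TRUE),
                 ci95 = c(diff - tc * se, diff + tc * se),
                 mean_diff = diff, variant = variant,
                 g1 = s1, g2 = s2),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s t-test: t(%s) = %.3f, p = %.4g, Cohen's d = %.2f\n",
              x$variant,
              format(round(x$df, 2)), x$t, x$p, x$d))
  cat(sprintf("  mean difference %.3f, 95%% CI [%.3f, %.3f]\n",
              x$mean_diff, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Cohen's d for independent groups (unweighted-variance form)
#'
#' `d = |m1 - m2| / sqrt((sd1^2 + sd2^2) / 2)`. The denominator averages
#' the two group variances without weighting by group size; with
#' `signed = TRUE` the sign of the mean difference is kept.
#'
#' @param g1,g2 Raw value vectors or [group_summary()] objects.
#' @param signed Keep the sign of `m1 - m2`? Default `FALSE` (magnitude).
#' @return Cohen's d.
#' @export
cohens_d_independent <- function(g1, g2, signed = FALSE) {
  s1 <- as_group_summary(g1); s2 <- as_group_summary(g2)
  if (s1$sd == 0 && s2$sd == 0) stop_user("both group SDs are zero")
  d <- (s1$mean - s2$mean) / sqrt((s1$sd^2 + s2$sd^2) / 2)
  if (signed) d else abs(d)
}

#' Paired t-test
#'
#' Two-sided t-test on within-subject differences, with Cohen's d =
#' mean(diff) / sd(diff).
#'
#' @param before,after Numeric vectors of equal length (n >= 2).
#' @param conf_level Confidence level for the mean-difference interval.
#' @return A `t_test_result` with `variant = "paired"`.
#' @export
paired_t <- function(before, after, conf_level = 0.95) {
  if (length(before) != length(after)) stop_user("paired samples differ in length")
  n <- length(before)
  if (n < 2) stop_user("need >= 2 pairs")
  d <- after - before
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (all(d == 0)) {
      # identical measurements: no change, by convention t = 0
      return(structure(list(t = 0, df = n - 1, p = 1, d = 0,
                            ci95 = c(0, 0), mean_diff = 0,
                            variant = "paired",
                            g1 = as_group_summary(before),
                            g2 = as_group_summary(after)),
                       class = "t_test_result"))
    }
    stop_user("zero variance of the paired differences")
  }
  se <- sd_d / sqrt(n)
  t <- mean(d) / se
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  tc <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(t = t, df = df, p = p, d = mean(d) / sd_d,
                 ci95 = c(mean(d) - tc * se, mean(d) + tc * se),
                 mean_diff = mean(d), variant = "paired",
                 g1 = as_group_summary(before), g2 = as_group_summary(after)),
            class = "t_test_result")
}

#' Hourly gain t-tests with false-discovery-rate correction
#'
#' Runs an independent t-test per ZT hour comparing two groups of
#' per-subject delta-gain series, then adjusts the hourly p-values with the
#' Benjamini-Hochberg procedure and flags hours at the given q threshold.
#'
#' @param gains_a,gains_b Lists of [delta_gain()] series (one per subject),
#'   or numeric matrices (subjects x hours) with ZT hours as column names.
#' @param variant t-test variant per hour (default `"welch"`).
#' @param q FDR threshold for the significance flags (default 0.05).
#' @return Data frame: `zt_hour`, `t`, `df`, `p_raw`, `p_adj`,
#'   `significant`, `n_a`, `n_b`.
#' @export
hourly_gain_tests_fdr <- function(gains_a, gains_b,
                                  variant = c("welch", "student"), q = 0.05) {
  variant <- match.arg(variant)
  A <- gains_to_matrix(gains_a)
  B <- gains_to_matrix(gains_b)
  hours <- intersect(colnames(A), colnames(B))
  if (!length(hours)) stop_user("the two groups share no ZT hours")
  res <- lapply(hours, function(h) {
    a <- A[, h]; a <- a[!is.na(a)]
    b <- B[, h]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(zt_hour = as.numeric(h), t = NA, df = NA,
                        p_raw = NA, n_a = length(a), n_b = length(b)))
    }
    tt <- independent_t(a, b, variant = variant)
    data.frame(zt_hour = as.numeric(h), t = tt$t, df = tt$df, p_raw = tt$p,
               n_a = length(a), n_b = length(b))
  })
  out <- do.call(rbind, res)
  out <- out[order(out$zt_hour), ]
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj <= q
  rownames(out) <- NULL
  out[, c("zt_hour", "t", "df", "p_raw", "p_adj", "significant", "n_a", "n_b")]
}

gains_to_matrix <- function(g) {
  if (is.matrix(g)) {
    if (is.null(colnames(g))) colnames(g) <- seq_len(ncol(g)) - 1
    return(g)
  }
  hours <- sort(unique(unlist(lapply(g, function(x) x$zt_hour))))
  m <- matrix(NA_real_, length(g), length(hours),
              dimnames = list(NULL, hours))
  for (i in seq_along(g)) {
    m[i, as.character(g[[i]]$zt_hour)] <- g[[i]]$gain_pp
  }
  m
}

#' Assumption screening: outliers, normality, variance homogeneity
#'
#' Per group: boxplot outlier flags (values beyond 1.5 x IQR from the
#' quartiles), sample skewness and excess kurtosis (bias-corrected, as
#' common statistical software reports them); across groups: Levene's test
#' with centre = mean.
#'
#' @param groups Named list of numeric vectors.
#' @return Object of class `assumption_screen`: list with `outliers`
#'   (per-group logical vectors), `moments` (data frame of skewness /
#'   kurtosis), `levene` (list: statistic, df, p).
#' @export
screen_assumptions <- function(groups) {
  if (!is.list(groups)) groups <- list(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  outliers <- lapply(groups, function(x) {
    qs <- stats::quantile(x, c(0.25, 0.75))
    iqr <- qs[2] - qs[1]
    x < qs[1] - 1.5 * iqr | x > qs[2] + 1.5 * iqr
  })
  moments <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 0L),
    skewness = vapply(groups, function(x) e1071::skewness(x, type = 2), 0),
    kurtosis = vapply(groups, function(x) e1071::kurtosis(x, type = 2), 0)
  )
  lev <- if (length(groups) >= 2 && all(vapply(groups, length, 0L) >= 3)) {
    levene_test(groups)
  } else NULL
  structure(list(outliers = outliers, moments = moments, levene = lev),
            class = "assumption_screen")
}

# Levene's test with centre = mean (classical form), via car.
levene_test <- function(groups) {
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0) {
    return(list(statistic = 0, df = c(length(groups) - 1,
                                      length(y) - length(groups)), p = 1))
  }
  res <- car::leveneTest(y, g, center = mean)
  list(statistic = res[1, "F value"],
       df = c(res[1, "Df"], res[2, "Df"]),
       p = res[1, "Pr(>F)"])
}

#' @export
print.assumption_screen <- function(x, ...) {
  cat("Assumption screen\n")
  print(x$moments, row.names = FALSE)
  n_out <- vapply(x$outliers, sum, 0L)
  cat("  boxplot outliers:", paste(sprintf("%s=%d", names(n_out), n_out),
                                   collapse = ", "), "\n")
  if (!is.null(x$levene)) {
    cat(sprintf("  Levene F(%d, %d) = %.3f, p = %.4g\n",
                x$levene$df[1], x$levene$df[2], x$levene$statistic,
                x$levene$p))
  }
  invisible(x)
}
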