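# Two-way ANOVA (genotype x treatment) with Type-III sums of squares,
# partial eta squared, and unadjusted (LSD-style) pairwise cell comparisons
# from the residual mean square.

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, the proportion of effect-plus-
#' error variance attributable to the effect.
#'
#' @param f F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @return Partial eta squared in [0, 1].
#' @export
#' @examples
#' partial_eta_sq_from_f(10.820, 1, 28)  # 0.279
partial_eta_sq_from_f <- function(f, df1, df2) {
  if (any(f < 0) || any(df1 < 1) || any(df2 < 1)) {
    stop_user("need F >= 0 and degrees of freedom >= 1")
  }
  f * df1 / (f * df1 + df2)
}

#' Two-way ANOVA with partial eta squared and pairwise comparisons
#'
#' Fits `value ~ A * B` with sum-to-zero contrasts and Type-III sums of
#' squares (unbalanced designs allowed), reports F, p and partial eta
#' squared per effect, and runs the four simple pairwise cell comparisons
#' (across `B` within each level of `A`, and across `A` within each level
#' of `B`) with standard errors from the residual mean square, unadjusted
#' p-values and 95% confidence intervals.
#'
#' @param values Numeric response vector.
#' @param a,b Factors (e.g. genotype and treatment) of the same length.
#' @param a_name,b_name Labels used in the output tables.
#' @return Object of class `anova_result`: list with `effects` (data frame:
#'   effect, F, df1, df2, p, partial_eta_sq), `pairwise` (data frame:
#'   comparison, difference, ci_lo, ci_hi, p), `cell_means`, `mse`,
#'   `df_resid`.
#' @export
two_way_anova <- function(values, a, b, a_name = "genotype",
                          b_name = "treatment") {
  a <- factor(a); b <- factor(b)
  if (length(values) != length(a) || length(values) != length(b)) {
    stop_user("`values`, `a` and `b` must have equal length")
  }
  tab <- table(a, b)
  if (any(tab == 0)) stop_user("empty design cell")
  if (sum(tab >= 2) < 3) stop_user("need >= 2 observations in >= 3 cells")
  dat <- data.frame(y = values, A = a, B = b)
  fit <- stats::lm(y ~ A * B, data = dat,
                   contrasts = list(A = "contr.sum", B = "contr.sum"))
  aov3 <- car::Anova(fit, type = 3)
  rows <- c("A", "B", "A:B")
  df2 <- aov3["Residuals", "Df"]
  eff <- data.frame(
    effect = c(a_name, b_name, paste0(a_name, ":", b_name)),
    F = aov3[rows, "F value"],
    df1 = aov3[rows, "Df"],
    df2 = df2,
    p = aov3[rows, "Pr(>F)"]
  )
  eff$partial_eta_sq <- partial_eta_sq_from_f(eff$F, eff$df1, eff$df2)
  mse <- aov3["Residuals", "Sum Sq"] / df2

  cm <- stats::aggregate(y ~ A + B, dat, mean)
  nn <- stats::aggregate(y ~ A + B, dat, length)
  cm$n <- nn$y
  pairs <- list()
  for (lv in levels(a)) {
    pairs[[length(pairs) + 1]] <- cell_compare(cm, mse, df2,
      i = cm$A == lv & cm$B == levels(b)[1],
      j = cm$A == lv & cm$B == levels(b)[2],
      label = sprintf("%s=%s: %s %s - %s", a_name, lv, b_name,
                      levels(b)[1], levels(b)[2]))
  }
  for (lv in levels(b)) {
    pairs[[length(pairs) + 1]] <- cell_compare(cm, mse, df2,
      i = cm$B == lv & cm$A == levels(a)[1],
      j = cm$B == lv & cm$A == levels(a)[2],
      label = sprintf("%s=%s: %s %s - %s", b_name, lv, a_name,
                      levels(a)[1], levels(a)[2]))
  }
  structure(list(effects = eff, pairwise = do.call(rbind, pairs),
                 cell_means = cm, mse = mse, df_resid = df2),
            class = "anova_result")
}

cell_compare <- function(cm, mse, df2, i, j, label) {
  d <- cm$y[i] - cm$y[j]
  se <- sqrt(mse * (1 / cm$n[i] + 1 / cm$n[j]))
  t <- d / se
  tc <- stats::qt(0.975, df2)
  data.frame(comparison = label, difference = d,
             ci_lo = d - tc * se, ci_hi = d + tc * se,
             p = 2 * stats::pt(-abs(t), df2))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Two-way ANOVA (Type III)\n")
  eff <- x$effects
  eff$F <- round(eff$F, 3); eff$p <- signif(eff$p, 3)
  eff$partial_eta_sq <- round(eff$partial_eta_sq, 3)
  print(eff, row.names = FALSE)
  cat("Pairwise comparisons (unadjusted, residual-MS SE):\n")
  pw <- x$pairwise
  pw[-1] <- lapply(pw[-1], function(v) round(v, 3))
  print(pw, row.names = FALSE)
  invisible(x)
}
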