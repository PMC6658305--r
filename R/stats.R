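#' @title Two-group and multi-group comparisons
#' @description
#' Welch two-sample tests for antipyretic vs no-antipyretic contrasts, and
#' one-way ANOVA across vaccines with a mean-centred Levene check of
#' variance homogeneity. The ANOVA F is reported even when Levene rejects —
#' the post hoc procedure (Dunnett T3) is what changes under
#' heteroscedasticity, not the omnibus report.
#' @name fever-stats
NULL

#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, two-sided.
#'
#' @param a,b Numeric samples, each of length at least 2.
#' @return Object of class `fever_ttest`: group means and SDs, mean
#'   difference (`a - b`), t statistic, Welch df, two-sided p, and a
#'   `degenerate` flag for the zero-variance corner.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  out <- list(mean_a = mean(a), mean_b = mean(b), sd_a = stats::sd(a),
              sd_b = stats::sd(b), n_a = length(a), n_b = length(b),
              mean_diff = mean(a) - mean(b), degenerate = FALSE)
  if (out$sd_a == 0 && out$sd_b == 0) {
    out$degenerate <- TRUE
    if (out$mean_diff == 0) {
      out$t <- 0; out$df <- NA_real_; out$p <- 1
    } else {
      out$t <- sign(out$mean_diff) * Inf; out$df <- NA_real_; out$p <- 0
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- tt$p.value
  }
  class(out) <- "fever_ttest"
  out
}

#' @export
print.fever_ttest <- function(x, ...) {
  cat(sprintf(
    "Welch t test: %.3f (n=%d, SD %.3f) vs %.3f (n=%d, SD %.3f)\n",
    x$mean_a, x$n_a, x$sd_a, x$mean_b, x$n_b, x$sd_b))
  cat(sprintf("  diff %.3f, t = %.3f on %.1f df, two-sided p = %.4g%s\n",
              x$mean_diff, x$t, x$df, x$p,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' One-way ANOVA with a Levene homogeneity check
#'
#' Classic one-way F test across groups, together with Levene's test on
#' absolute deviations from the group means — the gate for choosing an
#' unequal-variance post hoc procedure.
#'
#' @param values Numeric response.
#' @param groups Grouping vector (coerced to factor), at least 2 groups of
#'   at least 2 observations each.
#' @return Object of class `fever_anova` with the F statistic, degrees of
#'   freedom, p value, Levene statistic and p, and per-group n/mean/SD.
#' @export
oneway_anova_levene <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups))[ok]
  groups <- droplevels(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs n >= 2")
  per_group <- data.frame(
    group = names(sizes), n = as.integer(sizes),
    mean = as.numeric(tapply(values, groups, mean)),
    sd = as.numeric(tapply(values, groups, stats::sd)),
    stringsAsFactors = FALSE)
  degenerate <- stats::var(values) == 0
  if (degenerate) {
    f <- 0; p <- NA_real_; lev_f <- 0; lev_p <- NA_real_
  } else {
    aovtab <- stats::anova(stats::lm(values ~ groups))
    f <- aovtab$`F value`[1]
    p <- aovtab$`Pr(>F)`[1]
    lev <- car::leveneTest(values, groups, center = mean)
    lev_f <- lev$`F value`[1]
    lev_p <- lev$`Pr(>F)`[1]
  }
  structure(list(
    f = f, df_between = length(sizes) - 1L,
    df_within = length(values) - length(sizes), p = p,
    levene_f = lev_f, levene_p = lev_p, per_group = per_group,
    degenerate = degenerate
  ), class = "fever_anova")
}

#' @export
print.fever_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F_(%d,%d) = %.2f, p = %.4g%s\n",
              x$df_between, x$df_within, x$f, x$p,
              if (x$degenerate) " (degenerate: constant response)" else ""))
  cat(sprintf("Levene (mean-centred): F = %.2f, p = %.4g\n",
              x$levene_f, x$levene_p))
  print(transform(x$per_group, mean = round(mean, 3), sd = round(sd, 3)),
        row.names = FALSE)
  invisible(x)
}
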