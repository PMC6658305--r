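#' @title High-fever logistic regression with VIF screening
#' @description
#' Models the probability of a relatively high fever (maximum temperature
#' at or above the high-fever threshold, 39.0 °C by default) as a function
#' of age, weight and sex, by binomial maximum likelihood (iteratively
#' reweighted least squares). Collinearity between age and weight — which
#' are strongly correlated in growing children — is screened with variance
#' inflation factors before fitting. Sex is coded female = 0 (reference),
#' male = 1.
#' @name fever-logistic
NULL

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R²_j)` where `R²_j` is from regressing predictor `j`
#' on the remaining predictors (auxiliary least squares). With exactly two
#' predictors the two VIFs coincide (shared R²). Exactly collinear
#' predictors yield an infinite VIF, flagged rather than fatal.
#'
#' @param design Numeric matrix or data frame of predictors (at least two
#'   non-constant columns).
#' @param vif_limit Threshold above which a predictor is flagged.
#' @return Data frame `predictor, vif, flagged` of class `fever_vif`.
#' @export
compute_vif <- function(design, vif_limit = 10) {
  X <- as.matrix(design)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  if (any(apply(X, 2, stats::var) == 0)) stop("constant predictor in design")
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out <- data.frame(predictor = colnames(X), vif = vif,
                    flagged = !is.finite(vif) | vif >= vif_limit,
                    stringsAsFactors = FALSE)
  class(out) <- c("fever_vif", "data.frame")
  out
}

# One-dimensional perfect-separation screen, per predictor.
separating_predictor <- function(X, y) {
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (max(x[y == 1]) <= min(x[y == 0]) ||
        max(x[y == 0]) <= min(x[y == 1])) {
      return(colnames(X)[j])
    }
  }
  NULL
}

#' Logistic regression for relatively high fever
#'
#' Fits `P(tmax >= high_fever_threshold)` on age (months), weight (kg) and
#' sex (male = 1) by IRLS with a tight convergence tolerance, reports Wald
#' standard errors, adjusted odds ratios with normal-quantile confidence
#' intervals (`exp(B ± 1.96 SE)`), and the pre-fit VIF screen.
#'
#' @param data Data frame with columns `tmax_c`, `age_months`, `weight_kg`
#'   and `sex` (`"male"`/`"female"`), e.g. surviving events joined to their
#'   episodes; see [high_fever_data()].
#' @param config A [fever_config()].
#' @param level Confidence level for the odds-ratio intervals.
#' @return Object of class `fever_logistic`: coefficient table (`B`, `SE`,
#'   Wald `z`, `p`, `or`, `or_lo`, `or_hi`), the VIF report, counts, and
#'   the underlying `glm` fit.
#' @export
fit_high_fever_logistic <- function(data, config = fever_config(),
                                    level = 0.95) {
  config <- as_fever_config(config)
  need <- c("tmax_c", "age_months", "weight_kg", "sex")
  stopifnot(all(need %in% names(data)))
  d <- data[stats::complete.cases(data[need]), need]
  y <- as.integer(d$tmax_c >= config$high_fever_threshold)
  if (sum(y) == 0 || sum(y) == nrow(d)) {
    stop("outcome has no events or no non-events")
  }
  X <- cbind(age_months = d$age_months, weight_kg = d$weight_kg,
             sex_male = as.integer(d$sex == "male"))
  if (any(apply(X, 2, stats::var) == 0)) stop("constant predictor")
  sep <- separating_predictor(X, y)
  if (!is.null(sep)) stop("perfect separation on predictor: ", sep)
  vif <- compute_vif(X[, c("age_months", "weight_kg")], config$vif_limit)

  fit <- stats::glm(y ~ age_months + weight_kg + sex_male,
                    family = stats::binomial(),
                    data = data.frame(y = y, X),
                    control = stats::glm.control(epsilon = 1e-10,
                                                 maxit = 100))
  if (!fit$converged) {
    stop("IRLS did not converge in ", fit$iter, " iterations")
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- data.frame(
    predictor = rownames(sm), B = sm[, 1], SE = sm[, 2],
    z = sm[, 3], p = sm[, 4],
    or = exp(sm[, 1]), or_lo = exp(sm[, 1] - z * sm[, 2]),
    or_hi = exp(sm[, 1] + z * sm[, 2]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, vif = vif, n = nrow(d),
                 n_events = sum(y), level = level, fit = fit),
            class = "fever_logistic")
}

#' Odds ratio and confidence interval from a coefficient
#'
#' Pure reconstruction `OR = exp(B)`, `CI = exp(B ± z SE)`; used to check
#' published coefficient tables against their printed odds ratios.
#'
#' @param b Log-odds coefficient.
#' @param se Its standard error.
#' @param level Confidence level.
#' @return Named numeric `or, lo, hi`.
#' @export
or_from_coef <- function(b, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(b), lo = exp(b - z * se), hi = exp(b + z * se))
}

#' Assemble the high-fever modelling frame
#'
#' Joins surviving events to their extracted episodes, yielding one row per
#' analyzable record with demographics and `tmax_c`.
#'
#' @param fr A `fever_records` object.
#' @param vaccine Optional single vaccine to subset to.
#' @return Data frame ready for [fit_high_fever_logistic()].
#' @export
high_fever_data <- function(fr, vaccine = NULL) {
  stopifnot(inherits(fr, "fever_records"))
  ev <- fr$events
  if (!is.null(vaccine)) ev <- ev[ev$vaccine == vaccine, , drop = FALSE]
  m <- match(ev$child_id, fr$episodes$child_id)
  data.frame(child_id = ev$child_id, vaccine = ev$vaccine,
             age_months = ev$age_months, weight_kg = ev$weight_kg,
             sex = ev$sex, tmax_c = fr$episodes$tmax_c[m],
             stringsAsFactors = FALSE)
}

#' @export
print.fever_logistic <- function(x, digits = 3, ...) {
  cat(sprintf(
    "High-fever logistic regression (n = %d, events = %d)\n", x$n,
    x$n_events))
  co <- x$coefficients
  co[-1] <- lapply(co[-1], signif, digits)
  print(co, row.names = FALSE)
  cat("VIF screen:\n")
  print(as.data.frame(x$vif), row.names = FALSE)
  invisible(x)
}
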