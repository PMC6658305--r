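#' @title Dunnett T3 pairwise comparisons
#' @description
#' Post hoc procedure for all pairwise mean comparisons under unequal
#' variances: each pair gets a Welch-type standardized mean difference with
#' Satterthwaite degrees of freedom, referred to the studentized maximum
#' modulus (SMM) distribution with `k(k-1)/2` comparisons. The SMM CDF is
#' evaluated by deterministic numerical integration over the chi
#' distribution of the denominator.
#' @name fever-dunnett
NULL

#' Studentized maximum modulus distribution
#'
#' CDF of `max_i |Z_i| / (chi_nu / sqrt(nu))` for `r` independent standard
#' normals and an independent chi on `nu` degrees of freedom:
#' `F(q) = E_W[(2 * pnorm(q * sqrt(W / nu)) - 1)^r]` with `W ~ chisq(nu)`,
#' computed by adaptive quadrature. `nu = Inf` reduces to the maximum of
#' `r` absolute normals.
#'
#' @param q Quantile (vectorised).
#' @param r Number of comparisons (independent normals).
#' @param nu Degrees of freedom of the chi denominator.
#' @return `P(SMM <= q)`.
#' @export
psmm <- function(q, r, nu) {
  stopifnot(r >= 1)
  one <- function(qi) {
    if (!is.finite(qi)) return(if (qi > 0) 1 else 0)
    if (qi <= 0) return(0)
    if (!is.finite(nu)) return((2 * stats::pnorm(qi) - 1)^r)
    f <- function(w) (2 * stats::pnorm(qi * sqrt(w / nu)) - 1)^r *
      stats::dchisq(w, nu)
    # integrate over the central chi-square mass: for large nu the density
    # is a narrow spike near w = nu which (0, Inf) quadrature can miss
    lo <- stats::qchisq(1e-13, nu)
    hi <- stats::qchisq(1 - 1e-13, nu)
    stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-12)$value
  }
  vapply(q, one, numeric(1))
}

#' Random draws from the studentized maximum modulus distribution
#'
#' Simulation counterpart of [psmm()]; used as an independent check of the
#' quadrature.
#'
#' @param n Number of draws.
#' @param r Number of comparisons.
#' @param nu Degrees of freedom.
#' @return Numeric vector of draws.
#' @export
rsmm <- function(n, r, nu) {
  z <- matrix(abs(stats::rnorm(n * r)), nrow = n)
  m <- apply(z, 1, max)
  if (is.finite(nu)) m <- m / sqrt(stats::rchisq(n, nu) / nu)
  m
}

welch_pair <- function(m1, s1, n1, m2, s2, n2) {
  se <- sqrt(s1^2 / n1 + s2^2 / n2)
  df <- se^4 / (s1^4 / (n1^2 * (n1 - 1)) + s2^4 / (n2^2 * (n2 - 1)))
  list(diff = m1 - m2, se = se, t = (m1 - m2) / se, df = df)
}

#' Dunnett T3 all-pairs post hoc test
#'
#' @param values Numeric response.
#' @param groups Grouping vector, at least 3 groups of at least 2 each
#'   (use [welch_t_test()] for two groups).
#' @param alpha Significance level for the grouping partition.
#' @return Object of class `fever_dunnett`: a pairwise table (mean
#'   difference, Welch-type SE, T3 statistic, Satterthwaite df, unadjusted
#'   Welch p, SMM-adjusted p) and `partition` — the groups ordered by
#'   decreasing mean, partitioned into blocks by connected components of
#'   the "not significantly different at alpha" relation.
#' @export
dunnett_t3 <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  lev <- levels(groups)
  k <- length(lev)
  if (k < 3) stop("need at least 3 groups; use welch_t_test() for two")
  sizes <- table(groups)
  if (any(sizes < 2)) stop("every group needs n >= 2")
  gm <- tapply(values, groups, mean)
  gs <- tapply(values, groups, stats::sd)
  gn <- as.integer(sizes)
  names(gn) <- lev
  r <- k * (k - 1) / 2
  pairs <- utils::combn(lev, 2)
  tab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    w <- welch_pair(gm[g1], gs[g1], gn[g1], gm[g2], gs[g2], gn[g2])
    data.frame(group1 = g1, group2 = g2, mean_diff = unname(w$diff),
               se = w$se, t3 = unname(w$t), df = w$df,
               p_welch = 2 * stats::pt(-abs(w$t), w$df),
               p_adjusted = min(1, 1 - psmm(abs(w$t), r, w$df)),
               stringsAsFactors = FALSE)
  }))
  tab$significant <- tab$p_adjusted < alpha

  # partition: connected components of the non-significance graph,
  # reported in order of decreasing group mean
  ord <- names(sort(gm, decreasing = TRUE))
  comp <- seq_len(k)
  names(comp) <- ord
  for (j in seq_len(nrow(tab))) {
    if (!tab$significant[j]) {
      c1 <- comp[tab$group1[j]]; c2 <- comp[tab$group2[j]]
      comp[comp == max(c1, c2)] <- min(c1, c2)
    }
  }
  partition <- unname(split(ord, factor(comp, levels = unique(comp[ord]))))

  structure(list(table = tab, partition = partition, alpha = alpha,
                 means = gm, sds = gs, n = gn),
            class = "fever_dunnett")
}

#' @export
print.fever_dunnett <- function(x, digits = 3, ...) {
  cat(sprintf("Dunnett T3 pairwise comparisons (%d groups, alpha = %g)\n",
              length(x$means), x$alpha))
  tab <- x$table
  tab$mean_diff <- round(tab$mean_diff, digits)
  tab$se <- round(tab$se, digits)
  tab$t3 <- round(tab$t3, 2)
  tab$df <- round(tab$df, 1)
  tab$p_welch <- signif(tab$p_welch, 3)
  tab$p_adjusted <- signif(tab$p_adjusted, 3)
  print(tab, row.names = FALSE)
  cat("Grouping (decreasing mean): ",
      paste(vapply(x$partition, paste, "", collapse = ", "),
            collapse = " > "), "\n")
  invisible(x)
}
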