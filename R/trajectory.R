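#' @title Onset-aligned temperature trajectories
#' @description
#' Reconstructs the mean course of postvaccination fever: every reading of
#' every analyzable record is re-expressed as hours relative to that
#' record's fever onset, binned into 1-hour bins over the trajectory window
#' (default -3 to +24 h), and summarised per (vaccine, antipyretic group)
#' as a mean with a t-based 95% confidence band. A straight line fitted to
#' the post-onset bin means quantifies the decay rate; antipyretic
#' suppression shows up as a flatter fitted slope.
#' @name fever-trajectory
NULL

#' Bin readings relative to fever onset
#'
#' By default readings are pooled within bins (every in-window reading
#' contributes one observation to its nearest integer bin centre). With
#' `per_record = TRUE` each record instead contributes its imputed curve
#' value at each bin centre its reading span covers (no extrapolation).
#'
#' @param fr A `fever_records` object from [apply_cascade()].
#' @param by Grouping: `"both"` (vaccine x antipyretic), `"antipyretic"`,
#'   `"vaccine"`, or `"none"`.
#' @param per_record Contribute imputed values at bin centres instead of
#'   pooled raw readings.
#' @return Data frame of class `fever_trajectory`: one row per group x bin
#'   with `n`, `mean_temp`, `ci_halfwidth` (0 when `n <= 1`).
#' @export
align_and_bin <- function(fr, by = c("both", "antipyretic", "vaccine",
                                     "none"),
                          per_record = FALSE) {
  stopifnot(inherits(fr, "fever_records"))
  by <- match.arg(by)
  cfg <- fr$config
  centers <- seq(ceiling(cfg$trajectory_window[1]),
                 floor(cfg$trajectory_window[2]))
  eps <- fr$episodes
  rd_split <- split(fr$readings[c("time_h", "temp_c")], fr$readings$child_id)

  rel <- vector("list", nrow(eps))
  for (i in seq_len(nrow(eps))) {
    r <- rd_split[[eps$child_id[i]]]
    rt <- resolve_ties(r$time_h, r$temp_c)
    if (per_record) {
      tt <- centers + eps$onset_h[i]
      cover <- tt >= rt$time_h[1] & tt <= rt$time_h[length(rt$time_h)]
      if (!any(cover)) next
      rel[[i]] <- data.frame(
        child_id = eps$child_id[i], center = centers[cover],
        temp_c = stats::approx(rt$time_h, rt$temp_c, xout = tt[cover])$y)
    } else {
      dt <- rt$time_h - eps$onset_h[i]
      ctr <- round(dt)
      keep <- abs(dt - ctr) <= 0.5 & ctr >= centers[1] &
        ctr <= centers[length(centers)]
      if (!any(keep)) next
      rel[[i]] <- data.frame(child_id = eps$child_id[i],
                             center = ctr[keep], temp_c = rt$temp_c[keep])
    }
  }
  rel <- do.call(rbind, rel)
  if (is.null(rel)) {
    rel <- data.frame(child_id = character(), center = numeric(),
                      temp_c = numeric())
  }
  m <- match(rel$child_id, eps$child_id)
  rel$vaccine <- eps$vaccine[m]
  rel$antipyretic <- eps$antipyretic_flag[m]
  grp <- switch(by,
    both = paste(rel$vaccine, ifelse(rel$antipyretic, "antipyretic",
                                     "no antipyretic"), sep = " / "),
    antipyretic = ifelse(rel$antipyretic, "antipyretic", "no antipyretic"),
    vaccine = rel$vaccine,
    none = rep("all", nrow(rel)))

  agg <- if (nrow(rel) == 0) {
    data.frame(group = character(), center = numeric(), n = integer(),
               mean_temp = numeric(), ci_halfwidth = numeric())
  } else {
    do.call(rbind, lapply(split(seq_len(nrow(rel)), list(grp, rel$center),
                                drop = TRUE), function(ix) {
      x <- rel$temp_c[ix]
      n <- length(x)
      hw <- if (n <= 1) 0 else
        stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
      data.frame(group = grp[ix[1]], center = rel$center[ix[1]], n = n,
                 mean_temp = mean(x), ci_halfwidth = hw,
                 stringsAsFactors = FALSE)
    }))
  }
  agg <- agg[order(agg$group, agg$center), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("fever_trajectory", "data.frame")
  agg
}

#' Linear decay fit through post-onset bin means
#'
#' Ordinary least squares of bin mean temperature on bin centre over
#' `[from_h, to_h]` hours relative to onset.
#'
#' @param traj A `fever_trajectory` (or compatible data frame with
#'   `center`, `mean_temp`); subset to one group first, or pass `group`.
#' @param from_h,to_h Fit range in hours relative to onset.
#' @param group Optional group label to subset `traj`.
#' @return List of class `fever_decay`: `slope` (°C/hour), `intercept`,
#'   `r_squared` (0 with `degenerate = TRUE` when the bin means are
#'   constant), `n_bins`.
#' @export
fit_decay <- function(traj, from_h = 0, to_h = 24, group = NULL) {
  d <- as.data.frame(traj)
  if (!is.null(group)) d <- d[d$group == group, , drop = FALSE]
  d <- d[d$center >= from_h & d$center <= to_h & d$n > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 non-empty bins in the fit range")
  fit <- stats::lm(mean_temp ~ center, data = d)
  sst <- sum((d$mean_temp - mean(d$mean_temp))^2)
  degenerate <- sst == 0
  r2 <- if (degenerate) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_bins = nrow(d),
                 degenerate = degenerate),
            class = "fever_decay")
}

#' @export
print.fever_decay <- function(x, ...) {
  cat(sprintf(
    "Post-onset decay: slope %.3f °C/h, R² = %.2f over %d bins%s\n",
    x$slope, x$r_squared, x$n_bins,
    if (x$degenerate) " (degenerate: constant bins)" else ""))
  invisible(x)
}

#' @export
plot.fever_trajectory <- function(x, ...) {
  groups <- unique(x$group)
  cols <- grDevices::hcl.colors(max(2, length(groups)), "Dark 2")
  graphics::plot(NULL, xlim = range(x$center),
                 ylim = range(c(x$mean_temp - x$ci_halfwidth,
                                x$mean_temp + x$ci_halfwidth)),
                 xlab = "hours from fever onset",
                 ylab = "body temperature (°C)", ...)
  for (i in seq_along(groups)) {
    d <- x[x$group == groups[i], ]
    graphics::lines(d$center, d$mean_temp, col = cols[i], lwd = 2)
    graphics::arrows(d$center, d$mean_temp - d$ci_halfwidth, d$center,
                     d$mean_temp + d$ci_halfwidth, length = 0.02,
                     angle = 90, code = 3, col = cols[i])
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   lwd = 2, bty = "n", cex = 0.8)
  graphics::abline(h = 38, lty = 3)
  invisible(x)
}
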