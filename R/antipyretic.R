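#' @title Antipyretic administration patterns
#' @description
#' Characterises caregiver dosing behaviour after vaccination: when the
#' first antipyretic is given (hourly histogram and cumulative curve over
#' the observation window) and at what body temperature (0.1 °C bins of
#' the imputed curve evaluated at the dose time).
#' @name fever-antipyretic
NULL

first_doses <- function(fr, all_doses = FALSE) {
  d <- fr$doses[order(fr$doses$child_id, fr$doses$time_h), , drop = FALSE]
  if (!all_doses) d <- d[!duplicated(d$child_id), , drop = FALSE]
  d
}

#' Timing of the first antipyretic dose
#'
#' @param fr A `fever_records` object from [apply_cascade()].
#' @param all_doses Use every dose rather than each record's first.
#' @return Object of class `fever_dose_timing`: hourly counts over the
#'   window, the fraction per bin (summing to 1), and the cumulative
#'   fraction curve.
#' @export
first_dose_timing <- function(fr, all_doses = FALSE) {
  stopifnot(inherits(fr, "fever_records"))
  d <- first_doses(fr, all_doses)
  if (nrow(d) == 0) stop("no doses in window")
  breaks <- seq(0, fr$config$window_hours, by = 1)
  counts <- as.numeric(table(cut(d$time_h, breaks, right = TRUE,
                                 include.lowest = TRUE)))
  frac <- counts / sum(counts)
  structure(list(hour = breaks[-1], counts = counts, fraction = frac,
                 cumulative = cumsum(frac), n = nrow(d)),
            class = "fever_dose_timing")
}

#' @export
print.fever_dose_timing <- function(x, ...) {
  cat(sprintf("First antipyretic dose timing (n = %d)\n", x$n))
  cat(sprintf("  within  1 h: %5.2f%%\n", 100 * x$cumulative[1]))
  cat(sprintf("  within 10 h: %5.2f%%\n", 100 * x$cumulative[10]))
  cat(sprintf("  within 24 h: %5.2f%%\n", 100 * x$cumulative[24]))
  invisible(x)
}

#' @export
plot.fever_dose_timing <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = x$hour,
                    xlab = "hours after vaccination",
                    ylab = "first doses", ...)
  invisible(x)
}

# 0.1 °C bin by round-half-away-from-zero (temperatures are positive).
bin_point1 <- function(x) floor(x * 10 + 0.5) / 10

#' Body temperature at antipyretic administration
#'
#' The temperature at each (first) dose is read off the record's imputed
#' curve at the dose time; doses outside the reading span fall back to the
#' nearest reading within 1 h, and are otherwise counted as unlocatable.
#'
#' @param fr A `fever_records` object.
#' @param all_doses Use every dose rather than first doses only.
#' @return Object of class `fever_dose_temps`: counts per 0.1 °C bin, the
#'   located temperatures, the fraction at or above the fever threshold,
#'   the fractions below 37 °C and above 40 °C, and the unlocatable count.
#' @export
temperature_at_dose <- function(fr, all_doses = FALSE) {
  stopifnot(inherits(fr, "fever_records"))
  d <- first_doses(fr, all_doses)
  rd_split <- split(fr$readings[c("time_h", "temp_c")], fr$readings$child_id)
  temp <- rep(NA_real_, nrow(d))
  for (i in seq_len(nrow(d))) {
    r <- rd_split[[d$child_id[i]]]
    if (is.null(r)) next
    rt <- resolve_ties(r$time_h, r$temp_c)
    t0 <- d$time_h[i]
    if (length(rt$time_h) >= 2 && t0 >= rt$time_h[1] &&
        t0 <= rt$time_h[length(rt$time_h)]) {
      temp[i] <- stats::approx(rt$time_h, rt$temp_c, xout = t0)$y
    } else {
      gap <- abs(rt$time_h - t0)
      j <- which.min(gap)
      if (length(j) == 1 && gap[j] <= 1) temp[i] <- rt$temp_c[j]
    }
  }
  located <- temp[!is.na(temp)]
  bins <- bin_point1(located)
  tab <- table(factor(sprintf("%.1f", bins)))
  thr <- fr$config$fever_threshold
  structure(list(
    bin_counts = tab, temps = located, n_doses = nrow(d),
    n_unlocatable = sum(is.na(temp)),
    frac_at_or_above_threshold = mean(located >= thr),
    frac_below_37 = mean(located < 37),
    frac_above_40 = mean(located > 40)
  ), class = "fever_dose_temps")
}

#' @export
print.fever_dose_temps <- function(x, ...) {
  cat(sprintf(
    "Temperature at first antipyretic dose (%d located, %d unlocatable)\n",
    length(x$temps), x$n_unlocatable))
  cat(sprintf("  at or above fever threshold: %.2f%%\n",
              100 * x$frac_at_or_above_threshold))
  cat(sprintf("  below 37 °C: %.2f%%   above 40 °C: %.2f%%\n",
              100 * x$frac_below_37, 100 * x$frac_above_40))
  invisible(x)
}
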