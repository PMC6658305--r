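#' @title Fever episode extraction
#' @description
#' The analytical core: given a vaccination record's irregular temperature
#' readings, impute the curve by piecewise-linear interpolation and find
#' the fever episode. Onset is the first time the imputed curve reaches the
#' fever threshold (exact linear inversion of the bracketing segment, not
#' grid search); if the very first reading is already febrile, onset is
#' that reading's time and the episode is flagged onset-censored. Offset is
#' the last time the curve falls below the threshold — absent when the
#' final reading is still febrile, in which case the record is not
#' analyzable. Duration is offset minus onset, spanning any sub-threshold
#' dips in between. Tmax is the maximum raw reading in the window (raw, not
#' imputed: interpolation can only stay at or below the larger endpoint).
#' @name fever-extract
NULL

#' Resolve duplicate reading times
#'
#' Readings sharing a time are collapsed to the maximum temperature at that
#' time (caregivers occasionally re-enter a measurement).
#'
#' @param time_h,temp_c Numeric vectors of equal length.
#' @return List `time_h`, `temp_c`, `n_collapsed` with sorted unique times.
#' @export
resolve_ties <- function(time_h, temp_c) {
  o <- order(time_h, -temp_c)
  time_h <- time_h[o]
  temp_c <- temp_c[o]
  keep <- !duplicated(time_h)
  list(time_h = time_h[keep], temp_c = temp_c[keep],
       n_collapsed = sum(!keep))
}

#' Piecewise-linear temperature curve
#'
#' Continuous interpolant through the readings: exact at every reading,
#' linear between neighbours, undefined (NA) outside the reading span — no
#' extrapolation.
#'
#' @param time_h,temp_c At least two readings, sorted, unique times.
#' @return A function `f(t)` of class `fever_curve`, with attributes
#'   `range` (the reading span) and the knots.
#' @export
impute_linear <- function(time_h, temp_c) {
  stopifnot(length(time_h) == length(temp_c))
  if (length(time_h) < 2) stop("need at least 2 readings to interpolate")
  if (is.unsorted(time_h)) {
    o <- order(time_h)
    time_h <- time_h[o]
    temp_c <- temp_c[o]
  }
  if (anyDuplicated(time_h)) {
    stop("duplicate reading times; resolve ties first")
  }
  f <- function(t) stats::approx(time_h, temp_c, xout = t, rule = 1)$y
  structure(f, range = range(time_h), time_h = time_h, temp_c = temp_c,
            class = c("fever_curve", "function"))
}

# First upward threshold crossing. Returns list(time, censored) or NULL.
onset_crossing <- function(time_h, temp_c, threshold) {
  idx <- which(temp_c >= threshold)
  if (length(idx) == 0) return(NULL)
  j <- idx[1]
  if (j == 1) return(list(time = time_h[1], censored = TRUE))
  t_on <- time_h[j - 1] + (threshold - temp_c[j - 1]) /
    (temp_c[j] - temp_c[j - 1]) * (time_h[j] - time_h[j - 1])
  list(time = t_on, censored = FALSE)
}

# Last downward threshold crossing; NULL when the final reading is febrile.
offset_crossing <- function(time_h, temp_c, threshold) {
  idx <- which(temp_c >= threshold)
  if (length(idx) == 0) return(NULL)
  j <- idx[length(idx)]
  if (j == length(time_h)) return(NULL)
  time_h[j] + (temp_c[j] - threshold) /
    (temp_c[j] - temp_c[j + 1]) * (time_h[j + 1] - time_h[j])
}

#' Extract the fever episode from one record's readings
#'
#' @param time_h,temp_c In-window readings (hours, °C); ties are resolved
#'   and readings sorted internally.
#' @param config A [fever_config()].
#' @return A one-row data frame `onset_h, offset_h, duration_h, tmax_c,
#'   onset_censored`, or `NULL` when the record has no fever episode with
#'   both onset and offset (absence is a value, not an error).
#' @examples
#' extract_episode(c(0, 6, 12), c(37, 39, 37))  # onset 3 h, offset 9 h
#' @export
extract_episode <- function(time_h, temp_c, config = fever_config()) {
  config <- as_fever_config(config)
  r <- resolve_ties(time_h, temp_c)
  if (length(r$time_h) < 2) return(NULL)
  on <- onset_crossing(r$time_h, r$temp_c, config$fever_threshold)
  if (is.null(on)) return(NULL)
  off <- offset_crossing(r$time_h, r$temp_c, config$fever_threshold)
  if (is.null(off)) return(NULL)
  data.frame(onset_h = on$time, offset_h = off,
             duration_h = off - on$time, tmax_c = max(r$temp_c),
             onset_censored = on$censored)
}

#' Keep single-vaccination records
#'
#' A vaccination is "single" when its (child, calendar date) group contains
#' exactly one record; same-day multiple vaccinations are all dropped.
#' Combination single-shot vaccines (DTaP, MMR) count as single. A child
#' with surviving single vaccinations on several distinct dates keeps only
#' the earliest — the temperature stream is anchored to one vaccination.
#'
#' @param events Vaccination events (see [read_vaccinations()]).
#' @return The surviving subset of `events`.
#' @export
select_single_vaccinations <- function(events) {
  if (nrow(events) == 0) return(events)
  day <- format(events$time, "%Y-%m-%d", tz = "UTC")
  key <- paste(events$child_id, day)
  single <- events[key %in% names(which(table(key) == 1)), , drop = FALSE]
  single <- single[order(single$child_id, single$time), , drop = FALSE]
  single[!duplicated(single$child_id), , drop = FALSE]
}

#' Apply the record-selection cascade
#'
#' Filters vaccination records through the analyzability stages, in order:
#' complete demographics → single vaccination → at least `min_readings`
#' readings in the window → an episode with both onset and offset →
#' vaccines with at least `min_records_per_vaccine` surviving records. Each
#' stage's survivor count is reported; counts are monotonically
#' non-increasing.
#'
#' @param readings,events,doses The three record streams.
#' @param config A [fever_config()].
#' @return Object of class `fever_records`: list with `events` (survivors,
#'   with `antipyretic_flag`), `readings` and `doses` (window-restricted,
#'   survivors only), `episodes` (one row per surviving record), `cascade`
#'   (named survivor counts) and `config`.
#' @export
apply_cascade <- function(readings, events, doses, config = fever_config()) {
  config <- as_fever_config(config)
  n_input <- nrow(events)

  has_demo <- !is.na(events$age_months) & !is.na(events$weight_kg) &
    !is.na(events$sex)
  ev <- events[has_demo, , drop = FALSE]
  n_demo <- nrow(ev)

  ev <- select_single_vaccinations(ev)
  n_single <- nrow(ev)

  win <- readings$time_h > 0 & readings$time_h <= config$window_hours &
    readings$child_id %in% ev$child_id
  rd <- readings[win, , drop = FALSE]
  rd <- rd[order(rd$child_id, rd$time_h), , drop = FALSE]
  # per-child tie resolution
  rd_split <- split(rd[c("time_h", "temp_c")], rd$child_id)
  rd_split <- lapply(rd_split, function(d) resolve_ties(d$time_h, d$temp_c))
  counts <- vapply(rd_split, function(d) length(d$time_h), integer(1))
  enough <- names(counts)[counts >= config$min_readings]
  ev <- ev[ev$child_id %in% enough, , drop = FALSE]
  n_readings <- nrow(ev)

  eps <- lapply(ev$child_id, function(id) {
    d <- rd_split[[id]]
    e <- extract_episode(d$time_h, d$temp_c, config)
    if (is.null(e)) return(NULL)
    cbind(data.frame(child_id = id, stringsAsFactors = FALSE), e)
  })
  episodes <- do.call(rbind, eps)
  if (is.null(episodes)) {
    episodes <- data.frame(child_id = character(), onset_h = numeric(),
                           offset_h = numeric(), duration_h = numeric(),
                           tmax_c = numeric(), onset_censored = logical())
  }
  ev <- ev[ev$child_id %in% episodes$child_id, , drop = FALSE]
  n_episode <- nrow(ev)

  vacc_n <- table(ev$vaccine)
  keep_vacc <- names(vacc_n)[vacc_n >= config$min_records_per_vaccine]
  ev <- ev[ev$vaccine %in% keep_vacc, , drop = FALSE]
  n_vaccine <- nrow(ev)

  dw <- doses[doses$time_h > 0 & doses$time_h <= config$window_hours &
                doses$child_id %in% ev$child_id, , drop = FALSE]
  ev$antipyretic_flag <- ev$child_id %in% dw$child_id
  episodes <- episodes[episodes$child_id %in% ev$child_id, , drop = FALSE]
  m <- match(episodes$child_id, ev$child_id)
  episodes$vaccine <- ev$vaccine[m]
  episodes$antipyretic_flag <- ev$antipyretic_flag[m]
  rd <- rd[rd$child_id %in% ev$child_id, , drop = FALSE]

  structure(list(
    events = ev, readings = rd, doses = dw, episodes = episodes,
    cascade = c(input = n_input, with_demographics = n_demo,
                single_vaccination = n_single,
                enough_readings = n_readings, with_episode = n_episode,
                vaccine_minimum = n_vaccine),
    config = config
  ), class = "fever_records")
}

#' @export
print.fever_records <- function(x, ...) {
  cat("Analyzable postvaccination records\n")
  cc <- x$cascade
  lab <- c("entered", "with demographics", "single vaccination",
           sprintf("≥ %d readings in window", x$config$min_readings),
           "episode with onset and offset",
           sprintf("vaccine with ≥ %d records",
                   x$config$min_records_per_vaccine))
  for (i in seq_along(cc)) cat(sprintf("  %-32s %6d\n", lab[i], cc[i]))
  if (nrow(x$events) > 0) {
    cat(sprintf("  antipyretic records: %d (%.1f%%)\n",
                sum(x$events$antipyretic_flag),
                100 * mean(x$events$antipyretic_flag)))
  }
  invisible(x)
}

iqr_width <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75))))
sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Cohort summary by vaccine
#'
#' Per-vaccine record and child counts, age and weight location/spread, sex
#' split, antipyretic share, readings per record, and reading temperatures —
#' the usual "basic characteristics" table — plus a Total row.
#'
#' @param fr A `fever_records` object from [apply_cascade()].
#' @return Data frame of class `fever_cohort_summary`.
#' @export
summarize_cohort <- function(fr) {
  stopifnot(inherits(fr, "fever_records"))
  if (nrow(fr$events) == 0) {
    groups <- character()
  } else {
    groups <- c(sort(unique(fr$events$vaccine)), "Total")
  }
  rows <- lapply(groups, function(v) {
    ev <- if (v == "Total") fr$events else
      fr$events[fr$events$vaccine == v, , drop = FALSE]
    rd <- fr$readings[fr$readings$child_id %in% ev$child_id, , drop = FALSE]
    per_rec <- as.numeric(table(factor(rd$child_id, levels = ev$child_id)))
    data.frame(
      vaccine = v, n_records = nrow(ev),
      n_children = length(unique(ev$child_id)),
      age_median = stats::median(ev$age_months), age_iqr = iqr_width(ev$age_months),
      age_mean = mean(ev$age_months), age_sd = sd0(ev$age_months),
      male_n = sum(ev$sex == "male"),
      male_pct = 100 * mean(ev$sex == "male"),
      weight_median = stats::median(ev$weight_kg),
      weight_iqr = iqr_width(ev$weight_kg),
      weight_mean = mean(ev$weight_kg), weight_sd = sd0(ev$weight_kg),
      antipyretic_n = sum(ev$antipyretic_flag),
      antipyretic_pct = 100 * mean(ev$antipyretic_flag),
      readings_mean = mean(per_rec), readings_sd = sd0(per_rec),
      temp_median = stats::median(rd$temp_c), temp_iqr = iqr_width(rd$temp_c),
      temp_mean = mean(rd$temp_c), temp_sd = sd0(rd$temp_c),
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    out <- data.frame(
      vaccine = character(), n_records = integer(), n_children = integer(),
      age_median = numeric(), age_iqr = numeric(), age_mean = numeric(),
      age_sd = numeric(), male_n = integer(), male_pct = numeric(),
      weight_median = numeric(), weight_iqr = numeric(),
      weight_mean = numeric(), weight_sd = numeric(),
      antipyretic_n = integer(), antipyretic_pct = numeric(),
      readings_mean = numeric(), readings_sd = numeric(),
      temp_median = numeric(), temp_iqr = numeric(), temp_mean = numeric(),
      temp_sd = numeric(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
  }
  class(out) <- c("fever_cohort_summary", "data.frame")
  out
}

#' @export
print.fever_cohort_summary <- function(x, digits = 1, ...) {
  cat("Cohort characteristics by vaccine\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
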