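#' @title CSV input and output for the three record streams
#' @description
#' Three longitudinal streams describe a cohort:
#' * `temperatures.csv` — `child_id, time_h, temp_c`: one caregiver
#'   measurement, time in hours since the anchoring vaccination.
#' * `vaccinations.csv` — `child_id, vaccine, time_iso8601, age_months,
#'   weight_kg, sex`: one vaccination instant with demographics.
#' * `doses.csv` — `child_id, agent, dose, time_h`: one antipyretic
#'   administration.
#'
#' Loading validates each row; invalid rows are rejected (with a row number
#' and reason) rather than silently analysed, and accepted + rejected counts
#' always add up to the input row count. Missing demographics are accepted
#' on load — the selection cascade filters them later.
#' @name fever-io
NULL

TEMP_HEADER <- c("child_id", "time_h", "temp_c")
VACC_HEADER <- c("child_id", "vaccine", "time_iso8601", "age_months",
                 "weight_kg", "sex")
DOSE_HEADER <- c("child_id", "agent", "dose", "time_h")
ISO_FMT <- "%Y-%m-%dT%H:%M:%SZ"

read_stream <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!identical(names(df), header)) {
    stop("malformed header in ", path, ": expected ",
         paste(header, collapse = ","), " but found ",
         paste(names(df), collapse = ","))
  }
  df
}

reject_frame <- function(rows = integer(), reasons = character()) {
  data.frame(row = as.integer(rows), reason = as.character(reasons),
             stringsAsFactors = FALSE)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Load a temperature-reading stream
#'
#' @param path Path to a `temperatures.csv` file (`child_id, time_h, temp_c`).
#' @param config A [fever_config()]; supplies the plausibility bounds.
#' @return A data frame `child_id, time_h, temp_c` of accepted rows, with a
#'   `rejections` attribute (data frame of row numbers and reasons).
#' @export
read_temperatures <- function(path, config = fever_config()) {
  config <- as_fever_config(config)
  raw <- read_stream(path, TEMP_HEADER)
  time_h <- num_or_na(raw$time_h)
  temp_c <- num_or_na(raw$temp_c)
  bad_time <- !is.finite(time_h)
  bad_temp <- !is.finite(temp_c) | temp_c < config$temp_bounds[1] |
    temp_c > config$temp_bounds[2]
  bad_id <- is.na(raw$child_id) | raw$child_id == ""
  reason <- rep(NA_character_, nrow(raw))
  reason[bad_temp] <- "temperature out of bounds"
  reason[bad_time] <- "non-finite time"
  reason[bad_id] <- "missing child_id"
  keep <- is.na(reason)
  out <- data.frame(child_id = raw$child_id[keep], time_h = time_h[keep],
                    temp_c = temp_c[keep], stringsAsFactors = FALSE)
  attr(out, "rejections") <- reject_frame(which(!keep), reason[!keep])
  out
}

#' Load a vaccination-event stream
#'
#' Rows with an unknown vaccine label or an unparseable timestamp are
#' rejected; missing demographics are kept as `NA` and handled by the
#' selection cascade.
#'
#' @param path Path to a `vaccinations.csv` file.
#' @return Data frame `child_id, vaccine, time, age_months, weight_kg, sex`
#'   (`time` is POSIXct, UTC) with a `rejections` attribute.
#' @export
read_vaccinations <- function(path) {
  raw <- read_stream(path, VACC_HEADER)
  time <- as.POSIXct(raw$time_iso8601, format = ISO_FMT, tz = "UTC")
  age <- num_or_na(raw$age_months)
  weight <- num_or_na(raw$weight_kg)
  sex <- ifelse(raw$sex %in% c("male", "female"), raw$sex, NA_character_)
  missing_txt <- function(x) is.na(x) | x == "" | x == "NA"
  reason <- rep(NA_character_, nrow(raw))
  reason[!missing_txt(raw$age_months) & is.na(age)] <- "unparseable age"
  reason[is.finite(age) & age < 0] <- "negative age"
  reason[is.finite(weight) & weight <= 0] <- "non-positive weight"
  reason[is.na(time)] <- "unparseable timestamp"
  reason[!(raw$vaccine %in% fever_vaccines)] <- "unknown vaccine"
  reason[is.na(raw$child_id) | raw$child_id == ""] <- "missing child_id"
  keep <- is.na(reason)
  out <- data.frame(child_id = raw$child_id[keep], vaccine = raw$vaccine[keep],
                    time = time[keep], age_months = age[keep],
                    weight_kg = weight[keep], sex = sex[keep],
                    stringsAsFactors = FALSE)
  attr(out, "rejections") <- reject_frame(which(!keep), reason[!keep])
  out
}

#' Load an antipyretic-dose stream
#'
#' @param path Path to a `doses.csv` file (`child_id, agent, dose, time_h`).
#' @return Data frame of accepted rows with a `rejections` attribute.
#' @export
read_doses <- function(path) {
  raw <- read_stream(path, DOSE_HEADER)
  time_h <- num_or_na(raw$time_h)
  dose <- num_or_na(raw$dose)
  reason <- rep(NA_character_, nrow(raw))
  reason[!is.finite(dose) | dose <= 0] <- "non-positive dose"
  reason[!is.finite(time_h)] <- "non-finite time"
  reason[is.na(raw$child_id) | raw$child_id == ""] <- "missing child_id"
  keep <- is.na(reason)
  out <- data.frame(child_id = raw$child_id[keep], agent = raw$agent[keep],
                    dose = dose[keep], time_h = time_h[keep],
                    stringsAsFactors = FALSE)
  attr(out, "rejections") <- reject_frame(which(!keep), reason[!keep])
  out
}

#' Load all three record streams
#'
#' @param path_temperatures,path_vaccinations,path_doses CSV paths.
#' @param config A [fever_config()].
#' @param quiet Suppress the acceptance/rejection message.
#' @return A list with elements `readings`, `events`, `doses` (each carrying
#'   a `rejections` attribute) and `rejections`, the combined rejection log.
#' @export
load_records <- function(path_temperatures, path_vaccinations, path_doses,
                         config = fever_config(), quiet = FALSE) {
  readings <- read_temperatures(path_temperatures, config)
  events <- read_vaccinations(path_vaccinations)
  doses <- read_doses(path_doses)
  tag <- function(stream, rej) {
    data.frame(stream = rep(stream, nrow(rej)), rej,
               stringsAsFactors = FALSE)
  }
  rej <- rbind(tag("temperatures", attr(readings, "rejections")),
               tag("vaccinations", attr(events, "rejections")),
               tag("doses", attr(doses, "rejections")))
  if (!quiet) {
    message(sprintf(
      "loaded %d readings, %d vaccinations, %d doses (%d rows rejected)",
      nrow(readings), nrow(events), nrow(doses), nrow(rej)))
  }
  list(readings = readings, events = events, doses = doses, rejections = rej)
}

#' Write record streams back to CSV
#'
#' Inverse of the readers: `load_records()` on the written files reproduces
#' the records field-for-field (times to 1e-9 h).
#'
#' @param readings,events,doses Data frames as returned by [load_records()]
#'   or [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths written.
#' @export
write_records <- function(readings, events, doses, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("unwritable path: ", dir)
  pt <- file.path(dir, "temperatures.csv")
  pv <- file.path(dir, "vaccinations.csv")
  pd <- file.path(dir, "doses.csv")
  fmt <- function(x) trimws(formatC(x, format = "g", digits = 15))
  utils::write.csv(
    data.frame(child_id = readings$child_id, time_h = fmt(readings$time_h),
               temp_c = fmt(readings$temp_c)),
    pt, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(child_id = events$child_id, vaccine = events$vaccine,
               time_iso8601 = format(events$time, ISO_FMT, tz = "UTC"),
               age_months = fmt(events$age_months),
               weight_kg = fmt(events$weight_kg), sex = events$sex),
    pv, row.names = FALSE, quote = TRUE)
  utils::write.csv(
    data.frame(child_id = doses$child_id, agent = doses$agent,
               dose = fmt(doses$dose), time_h = fmt(doses$time_h)),
    pd, row.names = FALSE, quote = TRUE)
  invisible(c(temperatures = pt, vaccinations = pv, doses = pd))
}
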