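# Shared fixtures and independent oracles, built in code.

# Policy with dosing and noise switched off and dense uniform sampling:
# the regime in which extraction should recover the latent pulse exactly.
nodose_policy <- function(noise = 0, rate = 4) {
  caregiver_policy(
    dose_probability_at_fever = 0, subthreshold_dose_probability = 0,
    never_dose_fraction = 1, noise_sd_c = noise, baseline_sd_c = 0.15,
    measurement_rate_base_per_h = rate, measurement_rate_febrile_per_h = rate)
}

# A triangular pulse with known geometry (apex at onset-anchored time).
make_pulse <- function(baseline = 36.8, fever = TRUE, onset = 10,
                       peak = 39.0, rise = 6, decay = 0.2) {
  feverpattern:::child_pulse(baseline, fever, onset, peak, rise, decay)
}

# Dense-grid brute-force crossing oracle: evaluate the interpolant on a
# fixed grid and take the first/last febrile grid point. Independent of the
# analytic segment inversion used by extract_episode().
grid_crossings <- function(time_h, temp_c, threshold = 38, step = 0.001) {
  g <- seq(time_h[1], time_h[length(time_h)], by = step)
  v <- stats::approx(time_h, temp_c, xout = g)$y
  idx <- which(v >= threshold)
  if (length(idx) == 0) return(NULL)
  offset <- if (idx[length(idx)] == length(g)) NA_real_ else g[idx[length(idx)]]
  list(onset = g[idx[1]], offset = offset)
}

severity_tiers <- list(c("hepatitis A", "influenza"),
                       c("Japanese encephalitis", "DTaP"),
                       "pneumococcus")

matches_tiers <- function(partition, tiers = severity_tiers) {
  length(partition) == length(tiers) &&
    all(mapply(setequal, partition, tiers))
}

# Readings that produce a clean episode: onset 3.5 h, offset 10 h.
febrile_profile <- function() {
  data.frame(time_h = c(1, 6, 9, 12, 20),
             temp_c = c(37, 39, 38.5, 37, 36.9))
}

afebrile_profile <- function() {
  data.frame(time_h = c(1, 6, 9, 12, 20),
             temp_c = c(36.9, 37.4, 37.2, 37.0, 36.8))
}

# Record-selection fixture with known per-stage survivorships:
# 60 entered -> 50 with demographics -> 40 single vaccinations ->
# 30 with >= 5 in-window readings -> 20 with an episode ->
# 13 after the per-vaccine minimum (10) drops the 7-record vaccine.
make_cascade_fixture <- function() {
  day <- function(i) as.POSIXct(sprintf("2016-01-%02d 09:00:00", i),
                                tz = "UTC")
  ev <- function(id, vaccine, time, age = 12) {
    data.frame(child_id = id, vaccine = vaccine, time = time,
               age_months = age, weight_kg = 0.4 * age + 4, sex = "male",
               stringsAsFactors = FALSE)
  }
  events <- list(); readings <- list()
  add_reading <- function(id, prof) {
    readings[[length(readings) + 1]] <<- cbind(child_id = id, prof)
  }
  n <- 0
  nid <- function() { n <<- n + 1; sprintf("F%03d", n) }

  for (i in 1:10) {  # no demographics
    e <- ev(nid(), "pneumococcus", day(1)); e$age_months <- NA
    events[[length(events) + 1]] <- e
  }
  for (i in 1:5) {   # same-day pairs: multiple vaccination, both dropped
    id <- nid()
    events[[length(events) + 1]] <- ev(id, "pneumococcus", day(2))
    events[[length(events) + 1]] <- ev(id, "DTaP", day(2))
  }
  for (i in 1:10) {  # single but only 3 in-window readings
    id <- nid()
    events[[length(events) + 1]] <- ev(id, "pneumococcus", day(3))
    add_reading(id, febrile_profile()[1:3, ])
  }
  for (i in 1:5) {   # enough readings, never febrile
    id <- nid()
    events[[length(events) + 1]] <- ev(id, "pneumococcus", day(4))
    add_reading(id, afebrile_profile())
  }
  for (i in 1:5) {   # febrile but still febrile at the last reading
    id <- nid()
    events[[length(events) + 1]] <- ev(id, "pneumococcus", day(5))
    p <- febrile_profile(); p$temp_c[4:5] <- c(38.6, 38.4)
    add_reading(id, p)
  }
  for (i in 1:13) {  # full survivors, majority vaccine
    id <- nid()
    events[[length(events) + 1]] <- ev(id, "pneumococcus", day(6))
    add_reading(id, febrile_profile())
  }
  for (i in 1:7) {   # full survivors, vaccine below the minimum of 10
    id <- nid()
    events[[length(events) + 1]] <- ev(id, "DTaP", day(7))
    add_reading(id, febrile_profile())
  }
  doses <- data.frame(child_id = sprintf("F%03d", 41:45),
                      agent = "acetaminophen", dose = 80, time_h = 7,
                      stringsAsFactors = FALSE)
  list(events = do.call(rbind, events), readings = do.call(rbind, readings),
       doses = doses,
       config = fever_config(min_records_per_vaccine = 10),
       expected = c(input = 60L, with_demographics = 50L,
                    single_vaccination = 40L, enough_readings = 30L,
                    with_episode = 20L, vaccine_minimum = 13L))
}

# Small analyzable fever_records object built from explicit profiles.
make_small_records <- function(n_children = 3, dose_time = NULL,
                               profile = febrile_profile()) {
  ids <- sprintf("S%02d", seq_len(n_children))
  events <- data.frame(
    child_id = ids, vaccine = "pneumococcus",
    time = as.POSIXct("2016-03-01 10:00:00", tz = "UTC") +
      86400 * seq_len(n_children),
    age_months = 10 + seq_len(n_children), weight_kg = 8 + seq_len(n_children),
    sex = rep(c("male", "female"), length.out = n_children),
    stringsAsFactors = FALSE)
  readings <- do.call(rbind, lapply(ids, function(id) {
    cbind(child_id = id, profile)
  }))
  doses <- if (is.null(dose_time)) {
    data.frame(child_id = character(), agent = character(),
               dose = numeric(), time_h = numeric())
  } else {
    data.frame(child_id = ids, agent = "acetaminophen", dose = 80,
               time_h = dose_time, stringsAsFactors = FALSE)
  }
  apply_cascade(readings, events, doses,
                fever_config(min_records_per_vaccine = 1))
}
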