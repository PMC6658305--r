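#' Per-vaccine fever kinetics
#'
#' One row per vaccine of the data-generating model behind the synthetic
#' cohort: the probability that a vaccination is followed by fever, the
#' latency from vaccination to fever onset (crossing 38.0 °C), the peak
#' temperature, and the shape of the triangular pulse (linear rise to the
#' peak, then linear decay). Latency is drawn from a lognormal distribution
#' with the stated mean and SD — caregiver-observed onset times are strongly
#' right-skewed (SD comparable to the mean) — and the peak from a normal
#' distribution truncated just above the fever threshold.
#'
#' @param vaccine Vaccine label (one of [fever_vaccines]).
#' @param fever_probability Probability in `[0, 1]` that fever occurs.
#' @param onset_latency_mean_h,onset_latency_sd_h Mean and SD (hours) of the
#'   latency from vaccination to the 38.0 °C crossing.
#' @param peak_temp_mean_c,peak_temp_sd_c Mean and SD (°C) of the peak.
#' @param rise_duration_h Hours from pulse start (baseline) to the peak.
#' @param decay_rate_c_per_h Post-peak linear decay rate (°C/hour).
#' @param share Relative frequency of the vaccine in a default cohort mix.
#' @param age_mean_months,age_sd_months Age-at-vaccination distribution
#'   (gamma, with these moments).
#' @return One-row data frame of class `vaccine_kinetics`.
#' @export
vaccine_kinetics <- function(vaccine, fever_probability,
                             onset_latency_mean_h, onset_latency_sd_h,
                             peak_temp_mean_c, peak_temp_sd_c,
                             rise_duration_h, decay_rate_c_per_h,
                             share = 1, age_mean_months = 15,
                             age_sd_months = 9) {
  stopifnot(
    vaccine %in% fever_vaccines,
    fever_probability >= 0, fever_probability <= 1,
    onset_latency_mean_h > 0, onset_latency_sd_h > 0,
    peak_temp_sd_c > 0, rise_duration_h > 0, decay_rate_c_per_h > 0,
    share > 0, age_mean_months > 0, age_sd_months > 0,
    "febrile vaccines need a peak above 38.0 °C" =
      fever_probability == 0 || peak_temp_mean_c > 38.0
  )
  out <- data.frame(
    vaccine = vaccine, fever_probability = fever_probability,
    onset_latency_mean_h = onset_latency_mean_h,
    onset_latency_sd_h = onset_latency_sd_h,
    peak_temp_mean_c = peak_temp_mean_c, peak_temp_sd_c = peak_temp_sd_c,
    rise_duration_h = rise_duration_h,
    decay_rate_c_per_h = decay_rate_c_per_h,
    share = share, age_mean_months = age_mean_months,
    age_sd_months = age_sd_months, stringsAsFactors = FALSE)
  class(out) <- c("vaccine_kinetics", "data.frame")
  out
}

#' Default five-vaccine kinetics table
#'
#' Defaults emulate, qualitatively, the published ordering of postvaccination
#' fever severity across the five commonly analysed vaccines — hepatitis A
#' and influenza hottest and longest, Japanese encephalitis and DTaP
#' intermediate, pneumococcus mildest and shortest — with onset latencies in
#' the 9–15 h range, peaks between 38.3 and 39.0 °C, and sub-threshold
#' return typically within 24 h of onset. Shares follow the relative record
#' frequencies reported for such cohorts (pneumococcus dominating). The
#' per-vaccine fever probability is not reported anywhere and is a stated
#' assumption (0.8 for all).
#'
#' @return A `vaccine_kinetics` table with five rows.
#' @export
default_kinetics <- function() {
  rbind(
    vaccine_kinetics("pneumococcus", 0.8, 9.0, 8, 38.33, 0.40, 6, 0.10,
                     share = 0.481, age_mean_months = 9.3,
                     age_sd_months = 8.1),
    vaccine_kinetics("Japanese encephalitis", 0.8, 11.5, 8, 38.67, 0.40, 6,
                     0.12, share = 0.212, age_mean_months = 19.1,
                     age_sd_months = 8.1),
    vaccine_kinetics("influenza", 0.8, 13.0, 9, 38.98, 0.40, 6, 0.14,
                     share = 0.155, age_mean_months = 28.0,
                     age_sd_months = 20.8),
    vaccine_kinetics("DTaP", 0.8, 10.5, 8, 38.65, 0.40, 6, 0.12,
                     share = 0.094, age_mean_months = 14.9,
                     age_sd_months = 13.0),
    vaccine_kinetics("hepatitis A", 0.8, 15.0, 10, 39.00, 0.40, 6, 0.13,
                     share = 0.058, age_mean_months = 20.4,
                     age_sd_months = 6.2)
  )
}

#' Caregiver measurement and dosing policy
#'
#' Behavioural model of the caregiver: how often temperature is measured
#' (more often when the child is febrile), when antipyretics are given, and
#' what a dose does to the temperature curve. A dose subtracts
#' `suppression_magnitude_c` from the latent temperature, decaying linearly
#' to zero over `suppression_duration_h` (default 4.4 h, the mean duration
#' of antipyretic effect observed in app-recorded cohorts), floored at the
#' child's baseline.
#'
#' A fraction `never_dose_fraction` of caregivers never administer
#' antipyretics; among the rest, each febrile reading (measured temperature
#' at or above `dose_threshold_c`) triggers a dose with probability
#' `dose_probability_at_fever`, and each sub-threshold reading with the
#' small probability `subthreshold_dose_probability`, never within
#' `redose_interval_min_h` of the previous dose. Defaults reproduce the
#' dosing pattern reported for caregiver apps that advise against dosing
#' below 38 °C: roughly nine in ten first doses at a measured temperature
#' of 38.0 °C or above, and about three quarters of febrile records dosed.
#'
#' @param dose_probability_at_fever Dose probability per febrile reading.
#' @param dose_threshold_c Measured temperature (°C) at which caregivers
#'   consider dosing.
#' @param suppression_magnitude_c Peak temperature reduction per dose (°C).
#' @param suppression_duration_h Hours over which the effect fades.
#' @param redose_interval_min_h Minimum hours between doses.
#' @param measurement_rate_base_per_h,measurement_rate_febrile_per_h
#'   Measurement intensities (events/hour) while the latent temperature is
#'   below / at-or-above the fever threshold.
#' @param subthreshold_dose_probability Dose probability per sub-threshold
#'   reading.
#' @param never_dose_fraction Fraction of caregivers who never dose.
#' @param noise_sd_c Gaussian measurement noise SD (°C).
#' @param baseline_mean_c,baseline_sd_c Distribution of the child's afebrile
#'   baseline temperature (°C).
#' @return Object of class `caregiver_policy`.
#' @export
caregiver_policy <- function(dose_probability_at_fever = 0.5,
                             dose_threshold_c = 38.0,
                             suppression_magnitude_c = 1.0,
                             suppression_duration_h = 4.4,
                             redose_interval_min_h = 6,
                             measurement_rate_base_per_h = 0.15,
                             measurement_rate_febrile_per_h = 1.2,
                             subthreshold_dose_probability = 0.04,
                             never_dose_fraction = 0.2,
                             noise_sd_c = 0.1,
                             baseline_mean_c = 36.8,
                             baseline_sd_c = 0.15) {
  pol <- as.list(environment())
  stopifnot(
    pol$dose_probability_at_fever >= 0, pol$dose_probability_at_fever <= 1,
    pol$subthreshold_dose_probability >= 0,
    pol$subthreshold_dose_probability <= 1,
    pol$never_dose_fraction >= 0, pol$never_dose_fraction <= 1,
    pol$suppression_duration_h > 0, pol$suppression_magnitude_c >= 0,
    pol$measurement_rate_base_per_h > 0,
    pol$measurement_rate_febrile_per_h > 0,
    pol$redose_interval_min_h >= 0, pol$noise_sd_c >= 0
  )
  class(pol) <- "caregiver_policy"
  pol
}

# Pulse parameters for one child. onset_h is the time the undosed curve
# crosses the fever threshold; the pulse is anchored so that happens exactly.
child_pulse <- function(baseline, has_fever, onset_h, peak_c, rise_h,
                        decay, threshold = 38.0) {
  if (!has_fever) {
    return(list(baseline = baseline, has_fever = FALSE, onset = NA_real_,
                t0 = NA_real_, tp = NA_real_, offset = NA_real_,
                peak = NA_real_, slope_up = NA_real_, decay = NA_real_))
  }
  slope_up <- (peak_c - baseline) / rise_h
  t0 <- onset_h - (threshold - baseline) / slope_up
  tp <- t0 + rise_h
  offset <- tp + (peak_c - threshold) / decay
  list(baseline = baseline, has_fever = TRUE, onset = onset_h, t0 = t0,
       tp = tp, offset = offset, peak = peak_c, slope_up = slope_up,
       decay = decay)
}

# Undosed latent temperature at times t (vectorised).
pulse_value <- function(pulse, t) {
  if (!pulse$has_fever) return(rep(pulse$baseline, length(t)))
  rise <- pulse$baseline + pulse$slope_up * (t - pulse$t0)
  fall <- pulse$peak - pulse$decay * (t - pulse$tp)
  val <- ifelse(t < pulse$t0, pulse$baseline, pmin(rise, fall))
  pmax(val, pulse$baseline)
}

# Total antipyretic suppression at times t given dose times (vectorised in t).
dose_suppression <- function(t, dose_times, policy) {
  if (length(dose_times) == 0) return(rep(0, length(t)))
  s <- vapply(t, function(ti) {
    el <- ti - dose_times
    sum(policy$suppression_magnitude_c *
          pmax(0, 1 - el / policy$suppression_duration_h) * (el >= 0))
  }, numeric(1))
  s
}

#' Latent (noiseless) temperature curve of a simulated child
#'
#' Baseline plus a triangular fever pulse (linear rise over the rise
#' duration to the child's peak, then linear decay), minus a linearly
#' fading suppression term for every antipyretic dose given so far, floored
#' at the baseline.
#'
#' @param child A child parameter list as produced by [draw_children()]
#'   (one element of its `pulse` column), or the output of `child_pulse()`.
#' @param t Hours since vaccination, inside `[0, window]`.
#' @param dose_times Numeric vector of dose times (hours).
#' @param policy A [caregiver_policy()].
#' @param window Observation window (hours).
#' @return Numeric vector of temperatures (°C) at `t`.
#' @export
latent_temperature <- function(child, t, dose_times = numeric(),
                               policy = caregiver_policy(), window = 48) {
  if (any(t < 0 | t > window)) stop("t outside the observation window")
  raw <- pulse_value(child, t) - dose_suppression(t, dose_times, policy)
  pmax(raw, child$baseline)
}
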