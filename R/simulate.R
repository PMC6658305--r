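#' @title Synthetic cohort simulator
#' @description
#' Generates seeded synthetic cohorts with the statistical structure the
#' downstream analysis assumes: irregular caregiver-driven measurement
#' times (an inhomogeneous point process, denser while the child is
#' febrile), vaccine-specific triangular fever pulses, threshold-triggered
#' antipyretic dosing with a transient linear suppression of the
#' temperature curve, and demographics with the age–weight correlation seen
#' in paediatric cohorts. Every record stream is CSV-ready and accompanied
#' by the noiseless ground truth, so extraction can be validated by
#' parameter recovery.
#' @name fever-simulate
NULL

rlnorm_ms <- function(n, mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

rtrunc_norm_lower <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Draw measurement times for one child
#'
#' Times come from an inhomogeneous Poisson process over `(0, window]`
#' realised by thinning: the intensity is the base rate while the undosed
#' latent temperature is below the fever threshold and the febrile rate
#' while at or above it.
#'
#' @param child Pulse parameter list (see [latent_temperature()]).
#' @param policy A [caregiver_policy()].
#' @param window Observation window in hours.
#' @param threshold Fever threshold (°C).
#' @return Sorted numeric vector of measurement times (hours).
#' @export
sample_measurement_times <- function(child, policy, window = 48,
                                     threshold = 38.0) {
  lmax <- max(policy$measurement_rate_base_per_h,
              policy$measurement_rate_febrile_per_h)
  m <- stats::rpois(1, lmax * window)
  if (m == 0) return(numeric())
  cand <- sort(stats::runif(m, 0, window))
  febrile <- pulse_value(child, cand) >= threshold
  rate <- ifelse(febrile, policy$measurement_rate_febrile_per_h,
                 policy$measurement_rate_base_per_h)
  cand[stats::runif(m) < rate / lmax]
}

#' Measured temperatures for one child
#'
#' Latent temperature (including any dose suppression) plus Gaussian
#' measurement noise, clipped to the plausible range.
#'
#' @inheritParams sample_measurement_times
#' @param times Measurement times; drawn via [sample_measurement_times()]
#'   when `NULL`.
#' @param dose_times Antipyretic dose times already given.
#' @param bounds Clipping bounds (°C).
#' @return Data frame `time_h`, `temp_c`.
#' @export
sample_measurements <- function(child, policy, times = NULL,
                                dose_times = numeric(), window = 48,
                                bounds = c(34, 43)) {
  if (is.null(times)) times <- sample_measurement_times(child, policy, window)
  lat <- latent_temperature(child, times, dose_times, policy, window)
  temp <- lat + stats::rnorm(length(times), 0, policy$noise_sd_c)
  data.frame(time_h = times,
             temp_c = pmin(pmax(temp, bounds[1]), bounds[2]))
}

# Sequential walk over readings: measured temperature reflects all doses
# given so far; dose decisions use the measured (noisy) temperature. This
# is the only stage that must be sequential — doses and measurements are
# mutually dependent.
observe_child <- function(child, times, policy, doser = TRUE, window = 48,
                          bounds = c(34, 43)) {
  n <- length(times)
  temp <- numeric(n)
  dose_times <- numeric(0)
  noise <- stats::rnorm(n, 0, policy$noise_sd_c)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    lat <- latent_temperature(child, times[i], dose_times, policy, window)
    temp[i] <- min(max(lat + noise[i], bounds[1]), bounds[2])
    if (!doser) next
    if (length(dose_times) > 0 &&
        times[i] - dose_times[length(dose_times)] <
          policy$redose_interval_min_h) next
    p <- if (temp[i] >= policy$dose_threshold_c) {
      policy$dose_probability_at_fever
    } else {
      policy$subthreshold_dose_probability
    }
    if (u[i] < p) dose_times <- c(dose_times, times[i])
  }
  list(times = times, temp = temp, dose_times = dose_times)
}

#' Simulate antipyretic dosing for one child
#'
#' At each reading whose measured temperature is at or above the dose
#' threshold, a dose occurs with the policy's febrile dose probability —
#' never within the minimum redose interval of the previous dose — and at
#' sub-threshold readings with the (small) sub-threshold probability.
#' Measured temperatures account for the suppression of doses already
#' given.
#'
#' @inheritParams sample_measurement_times
#' @param reading_times Sorted measurement times (hours).
#' @param doser Whether this caregiver doses at all.
#' @return Numeric vector of dose times, with the measured temperatures at
#'   all readings attached as attribute `"measured"`.
#' @export
simulate_doses <- function(child, reading_times, policy, doser = TRUE,
                           window = 48) {
  obs <- observe_child(child, reading_times, policy, doser, window)
  structure(obs$dose_times, measured = obs$temp)
}

#' Simulate a postvaccination cohort
#'
#' Generates the three record streams (temperature readings, vaccination
#' events with demographics, antipyretic doses) plus the per-child ground
#' truth of the undosed latent fever curve. Deterministic given `seed`.
#'
#' Demographics: age is gamma-distributed with the vaccine-specific moments
#' from the kinetics table; weight follows the linear age–weight relation
#' `0.4 * age_months + 4` plus 1 kg Gaussian noise; 60% of children are
#' male. Ground truth (onset, offset, duration, peak) describes the
#' noiseless, undosed pulse — doses depend on the noisy measurements, so
#' truth is defined before caregiver behaviour.
#'
#' @param n_children Number of vaccination records (one child each).
#' @param kinetics A kinetics table, see [default_kinetics()].
#' @param policy A [caregiver_policy()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param vaccine Optional character vector of vaccine assignments
#'   (recycled to `n_children`); defaults to sampling by the kinetics
#'   `share` weights. Unknown vaccines are an error.
#' @param window Observation window (hours).
#' @return Object of class `fever_cohort`: list with data frames
#'   `readings`, `events`, `doses`, `truth`.
#' @export
simulate_cohort <- function(n_children, kinetics = default_kinetics(),
                            policy = caregiver_policy(), seed = NULL,
                            vaccine = NULL, window = 48) {
  stopifnot(n_children >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(vaccine)) {
    vacc <- sample(kinetics$vaccine, n_children, replace = TRUE,
                   prob = kinetics$share)
  } else {
    if (!all(vaccine %in% kinetics$vaccine)) {
      stop("unknown vaccine: ",
           paste(setdiff(vaccine, kinetics$vaccine), collapse = ", "))
    }
    vacc <- rep_len(vaccine, n_children)
  }
  krow <- match(vacc, kinetics$vaccine)

  child_id <- sprintf("C%05d", seq_len(n_children))
  age <- stats::rgamma(n_children,
                       shape = (kinetics$age_mean_months[krow] /
                                  kinetics$age_sd_months[krow])^2,
                       rate = kinetics$age_mean_months[krow] /
                         kinetics$age_sd_months[krow]^2)
  weight <- pmax(0.4 * age + 4 + stats::rnorm(n_children, 0, 1), 2.5)
  sex <- ifelse(stats::runif(n_children) < 0.6, "male", "female")
  anchor <- as.POSIXct("2015-07-01 00:00:00", tz = "UTC") +
    round(stats::runif(n_children, 0, 730 * 86400))

  baseline <- pmin(pmax(stats::rnorm(n_children, policy$baseline_mean_c,
                                     policy$baseline_sd_c), 36.3), 37.4)
  fever <- stats::runif(n_children) < kinetics$fever_probability[krow]
  onset <- rlnorm_ms(n_children, kinetics$onset_latency_mean_h[krow],
                     kinetics$onset_latency_sd_h[krow])
  peak <- rtrunc_norm_lower(n_children, kinetics$peak_temp_mean_c[krow],
                            kinetics$peak_temp_sd_c[krow], 38.05)
  doser <- stats::runif(n_children) >= policy$never_dose_fraction

  r_id <- vector("list", n_children)
  r_t <- vector("list", n_children)
  r_temp <- vector("list", n_children)
  d_id <- vector("list", n_children)
  d_t <- vector("list", n_children)
  d_mg <- vector("list", n_children)
  onset_true <- offset_true <- peak_true <- rep(NA_real_, n_children)

  for (i in seq_len(n_children)) {
    pulse <- child_pulse(baseline[i], fever[i], onset[i], peak[i],
                         kinetics$rise_duration_h[krow[i]],
                         kinetics$decay_rate_c_per_h[krow[i]])
    if (fever[i]) {
      onset_true[i] <- pulse$onset
      offset_true[i] <- pulse$offset
      peak_true[i] <- pulse_value(pulse, min(max(pulse$tp, 0), window))
    }
    times <- sample_measurement_times(pulse, policy, window)
    obs <- observe_child(pulse, times, policy, doser[i], window)
    r_id[[i]] <- rep(child_id[i], length(times))
    r_t[[i]] <- obs$times
    r_temp[[i]] <- obs$temp
    nd <- length(obs$dose_times)
    if (nd > 0) {
      d_id[[i]] <- rep(child_id[i], nd)
      d_t[[i]] <- obs$dose_times
      d_mg[[i]] <- rep(round(12.5 * weight[i]), nd)
    }
  }

  readings <- data.frame(child_id = unlist(r_id),
                         time_h = unlist(r_t), temp_c = unlist(r_temp),
                         stringsAsFactors = FALSE)
  events <- data.frame(child_id = child_id, vaccine = vacc, time = anchor,
                       age_months = age, weight_kg = weight, sex = sex,
                       stringsAsFactors = FALSE)
  doses <- data.frame(child_id = unlist(d_id) %||% character(),
                      agent = rep("acetaminophen", length(unlist(d_t))),
                      dose = unlist(d_mg) %||% numeric(),
                      time_h = unlist(d_t) %||% numeric(),
                      stringsAsFactors = FALSE)
  truth <- data.frame(child_id = child_id, vaccine = vacc, fever = fever,
                      onset_h = onset_true, offset_h = offset_true,
                      duration_h = offset_true - onset_true,
                      peak_c = peak_true, stringsAsFactors = FALSE)
  structure(list(readings = readings, events = events, doses = doses,
                 truth = truth, seed = seed, window = window),
            class = "fever_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fever_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic postvaccination cohort: %d children, %d readings, %d doses\n",
    nrow(x$events), nrow(x$readings), nrow(x$doses)))
  cat(sprintf("  febrile (ground truth): %d (%.1f%%)\n",
              sum(x$truth$fever), 100 * mean(x$truth$fever)))
  print(table(x$events$vaccine))
  invisible(x)
}
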