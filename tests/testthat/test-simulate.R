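test_that("latent curve is baseline without fever and peaks by construction", {
  none <- make_pulse(fever = FALSE)
  t <- seq(0, 48, by = 0.5)
  expect_equal(latent_temperature(none, t), rep(36.8, length(t)))

  pulse <- make_pulse(onset = 10, peak = 39.0, rise = 6, decay = 0.2)
  expect_equal(latent_temperature(pulse, pulse$tp), 39.0)
  expect_equal(latent_temperature(pulse, pulse$onset), 38.0)
  expect_error(latent_temperature(pulse, 50), "outside")
})

test_that("dose suppression is a linear ramp subtracted from the pulse", {
  pulse <- make_pulse(onset = 10, peak = 39.0, rise = 6, decay = 0.2)
  pol <- caregiver_policy(suppression_magnitude_c = 1.0,
                          suppression_duration_h = 4.4)
  apex <- pulse$tp
  undosed <- latent_temperature(pulse, apex + 2.2, policy = pol)
  dosed <- latent_temperature(pulse, apex + 2.2, dose_times = apex,
                              policy = pol)
  expect_equal(undosed - dosed, 0.5)  # half the ramp remains at half-life
  # floored at baseline: a huge dose cannot push below baseline
  big <- caregiver_policy(suppression_magnitude_c = 10)
  expect_equal(latent_temperature(pulse, apex + 0.01, dose_times = apex,
                                  policy = big), 36.8)
})

test_that("zero-noise measurements lie exactly on the latent curve", {
  pulse <- make_pulse()
  pol <- nodose_policy(noise = 0, rate = 2)
  set.seed(5)
  rd <- sample_measurements(pulse, pol)
  expect_gt(nrow(rd), 10)
  expect_equal(rd$temp_c, latent_temperature(pulse, rd$time_h),
               tolerance = 1e-12)
})

test_that("febrile measurement intensity scales as configured", {
  pulse <- make_pulse(onset = 10, peak = 39.5, rise = 6, decay = 0.25)
  pol <- caregiver_policy(measurement_rate_base_per_h = 0.5,
                          measurement_rate_febrile_per_h = 2.0)
  feb_len <- pulse$offset - pulse$onset
  base_len <- 48 - feb_len
  set.seed(11)
  n_feb <- n_base <- 0
  for (s in 1:200) {
    tt <- sample_measurement_times(pulse, pol)
    feb <- tt >= pulse$onset & tt <= pulse$offset
    n_feb <- n_feb + sum(feb)
    n_base <- n_base + sum(!feb)
  }
  ratio <- (n_feb / feb_len) / (n_base / base_len)
  expect_gt(ratio, 3.5)  # configured 4x, Monte Carlo slack
  expect_lt(ratio, 4.5)
})

test_that("afebrile children are sampled at the base rate only", {
  none <- make_pulse(fever = FALSE)
  pol <- caregiver_policy(measurement_rate_base_per_h = 0.5,
                          measurement_rate_febrile_per_h = 2.0)
  set.seed(3)
  counts <- replicate(300, length(sample_measurement_times(none, pol)))
  expect_equal(mean(counts), 0.5 * 48, tolerance = 0.05)
})

test_that("dosing decisions follow the policy exactly at the corners", {
  pulse <- make_pulse(onset = 5, peak = 39.5, rise = 6, decay = 0.2)
  never <- caregiver_policy(dose_probability_at_fever = 0,
                            subthreshold_dose_probability = 0, noise_sd_c = 0)
  always <- caregiver_policy(dose_probability_at_fever = 1,
                             subthreshold_dose_probability = 0,
                             noise_sd_c = 0)
  times <- c(2, pulse$tp)  # one afebrile, one febrile reading
  set.seed(1)
  expect_length(as.numeric(simulate_doses(pulse, times, never)), 0)
  d <- simulate_doses(pulse, times, always)
  expect_equal(as.numeric(d), pulse$tp)
  expect_equal(attr(d, "measured")[2],
               latent_temperature(pulse, pulse$tp))
})

test_that("redosing is blocked within the minimum interval", {
  pulse <- make_pulse(onset = 2, peak = 39.8, rise = 6, decay = 0.05)
  pol <- caregiver_policy(dose_probability_at_fever = 1,
                          subthreshold_dose_probability = 0, noise_sd_c = 0,
                          redose_interval_min_h = 6)
  times <- seq(4, 20, by = 1)  # febrile throughout
  set.seed(1)
  d <- as.numeric(simulate_doses(pulse, times, pol))
  expect_true(all(diff(d) >= 6))
})

test_that("the cohort generator is deterministic given a seed", {
  a <- simulate_cohort(60, seed = 99)
  b <- simulate_cohort(60, seed = 99)
  expect_identical(a$readings, b$readings)
  expect_identical(a$events, b$events)
  expect_identical(a$doses, b$doses)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_cohort(10, vaccine = "smallpox"), "unknown vaccine")
})

test_that("a fever-free configuration yields zero episodes downstream", {
  kin <- default_kinetics()
  kin$fever_probability <- 0
  co <- simulate_cohort(80, kinetics = kin, seed = 4)
  fr <- apply_cascade(co$readings, co$events, co$doses,
                      fever_config(min_records_per_vaccine = 1))
  expect_equal(nrow(fr$episodes), 0)
  expect_equal(unname(fr$cascade["with_episode"]), 0)
})

test_that("demographics carry the programmed age-weight relation", {
  co <- simulate_cohort(2000, seed = 21)
  fit <- stats::lm(weight_kg ~ age_months, data = co$events)
  expect_equal(unname(coef(fit)[2]), 0.4, tolerance = 0.02)
  expect_equal(unname(coef(fit)[1]), 4, tolerance = 0.3)
  expect_equal(mean(co$events$sex == "male"), 0.6, tolerance = 0.03)
})

test_that("stronger antipyretic suppression lowers extracted Tmax
           monotonically", {
  mean_tmax <- function(mag, seed) {
    pol <- caregiver_policy(suppression_magnitude_c = mag)
    co <- simulate_cohort(120, policy = pol, seed = seed,
                          vaccine = "influenza")
    fr <- apply_cascade(co$readings, co$events, co$doses,
                        fever_config(min_records_per_vaccine = 1))
    mean(fr$episodes$tmax_c)
  }
  mags <- c(0.3, 1.0, 1.7)
  means <- sapply(mags, function(m) {
    mean(sapply(1:50, function(s) mean_tmax(m, 7000 + s)))
  })
  expect_true(all(diff(means) < 0))
})
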