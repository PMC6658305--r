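test_that("linear imputation is exact at readings and linear between them", {
  f <- impute_linear(c(0, 6), c(37, 39))
  expect_equal(f(3), 38.0)
  expect_equal(f(c(0, 6)), c(37, 39))
  expect_true(is.na(f(7)))  # no extrapolation
  expect_error(impute_linear(2, 38), "at least 2")
  expect_error(impute_linear(c(1, 1, 2), c(37, 38, 39)), "duplicate")
})

test_that("threshold crossings are inverted exactly on the worked example", {
  ep <- extract_episode(c(0, 6, 12), c(37, 39, 37))
  expect_equal(ep$onset_h, 3.0)
  expect_equal(ep$offset_h, 9.0)
  expect_equal(ep$duration_h, 6.0)
  expect_equal(ep$tmax_c, 39.0)
  expect_false(ep$onset_censored)
})

test_that("a first reading already febrile censors the onset", {
  ep <- extract_episode(c(2, 5, 10), c(38.5, 39, 37.5))
  expect_true(ep$onset_censored)
  expect_equal(ep$onset_h, 2.0)
  expect_equal(ep$offset_h, 5 + (39 - 38) / (39 - 37.5) * 5)  # 8.333...
  expect_equal(ep$duration_h, ep$offset_h - 2, tolerance = 1e-12)
})

test_that("records without a complete episode yield none, not an error", {
  expect_null(extract_episode(c(1, 5, 9), c(37, 37.5, 37.2)))  # no fever
  expect_null(extract_episode(c(1, 5, 9), c(37, 38.5, 38.2)))  # no offset
  expect_null(extract_episode(3, 38.5))                        # one reading
})

test_that("duration spans sub-threshold dips between multiple crossings", {
  ep <- extract_episode(c(0, 2, 4, 6, 8), c(37, 39, 37.5, 39, 37))
  expect_equal(ep$onset_h, 1.0)   # first upward crossing
  expect_equal(ep$offset_h, 7.0)  # last downward crossing
  expect_equal(ep$duration_h, 6.0)
})

test_that("inserting a collinear reading changes nothing", {
  t0 <- c(0, 6, 12); y0 <- c(37, 39, 37)
  ep0 <- extract_episode(t0, y0)
  ep1 <- extract_episode(c(0, 3, 6, 12), c(37, 38, 39, 37))
  expect_equal(ep0, ep1)
})

test_that("duplicate reading times collapse to the maximum temperature", {
  r <- resolve_ties(c(1, 2, 2, 3), c(37, 38.2, 37.9, 37))
  expect_equal(r$time_h, c(1, 2, 3))
  expect_equal(r$temp_c, c(37, 38.2, 37))
  expect_equal(r$n_collapsed, 1)
})

test_that("interpolated crossings agree with the dense-grid oracle", {
  set.seed(1234)
  for (i in 1:100) {
    n <- sample(5:10, 1)
    tt <- sort(stats::runif(n, 0, 48))
    yy <- stats::runif(n, 36.5, 39.5)
    ep <- extract_episode(tt, yy)
    or <- grid_crossings(tt, yy)
    if (is.null(or)) {
      expect_null(ep)
    } else if (is.na(or$offset)) {
      expect_null(ep)
    } else {
      expect_lt(abs(ep$onset_h - or$onset), 0.002)
      expect_lt(abs(ep$offset_h - or$offset), 0.002)
    }
  }
})

test_that("single vaccinations are kept, same-day multiples dropped", {
  day <- function(d) as.POSIXct(sprintf("2016-02-%02d 10:00:00", d),
                                tz = "UTC")
  ev <- data.frame(
    child_id = c("a", "a", "b", "b", "c", "d", "e"),
    vaccine = c("DTaP", "polio", "MMR", "Hib", "DTaP", "influenza",
                "pneumococcus"),
    time = c(day(1), day(1), day(2), day(2), day(3), day(4), day(5)),
    age_months = 12, weight_kg = 9, sex = "male", stringsAsFactors = FALSE)
  kept <- select_single_vaccinations(ev)
  expect_equal(sort(kept$child_id), c("c", "d", "e"))
  # a lone combination vaccine counts as a single vaccination
  expect_true("c" %in% kept$child_id && kept$vaccine[kept$child_id == "c"] ==
                "DTaP")
})

test_that("the selection cascade reproduces constructed survivorships", {
  fx <- make_cascade_fixture()
  fr <- apply_cascade(fx$readings, fx$events, fx$doses, fx$config)
  expect_identical(fr$cascade, fx$expected)
  expect_true(all(diff(fr$cascade) <= 0))
  # antipyretic flag reflects in-window doses of surviving records
  expect_equal(sum(fr$events$antipyretic_flag), 5)
  expect_equal(nrow(fr$episodes), 13)
  expect_true(all(fr$episodes$vaccine == "pneumococcus"))
})

test_that("the cascade is monotone on simulated cohorts and readings at
           the vaccination instant are excluded", {
  co <- simulate_cohort(150, seed = 17)
  rd <- rbind(co$readings,
              data.frame(child_id = co$events$child_id[1], time_h = 0,
                         temp_c = 37.0))
  fr <- apply_cascade(rd, co$events, co$doses,
                      fever_config(min_records_per_vaccine = 1))
  expect_true(all(diff(fr$cascade) <= 0))
  expect_false(any(fr$readings$time_h <= 0))
  expect_true(all(fr$readings$time_h <= 48))
})

test_that("Tmax sits between onset and offset on unimodal noiseless data", {
  co <- simulate_cohort(120, policy = nodose_policy(noise = 0, rate = 1.5),
                        seed = 23)
  fr <- apply_cascade(co$readings, co$events, co$doses,
                      fever_config(min_records_per_vaccine = 1))
  eps <- fr$episodes[!fr$episodes$onset_censored, ]
  for (i in seq_len(nrow(eps))) {
    rd <- fr$readings[fr$readings$child_id == eps$child_id[i], ]
    t_at_max <- rd$time_h[which.max(rd$temp_c)]
    expect_gte(t_at_max, eps$onset_h[i])
    expect_lte(t_at_max, eps$offset_h[i])
  }
})

test_that("noiseless dense extraction recovers ground truth per record", {
  co <- simulate_cohort(150, policy = nodose_policy(noise = 0, rate = 4),
                        seed = 29)
  fr <- apply_cascade(co$readings, co$events, co$doses,
                      fever_config(min_records_per_vaccine = 1))
  eps <- fr$episodes
  tr <- co$truth[match(eps$child_id, co$truth$child_id), ]
  expect_gt(nrow(eps), 50)
  expect_lt(mean(abs(eps$onset_h - tr$onset_h)), 0.1)
  expect_lt(mean(abs(eps$offset_h - tr$offset_h)), 0.1)
  expect_lt(mean(abs(eps$tmax_c - tr$peak_c)), 0.05)
})

test_that("cohort summary handles empty and singleton inputs", {
  fx <- make_cascade_fixture()
  empty <- apply_cascade(fx$readings, fx$events[0, ], fx$doses, fx$config)
  s0 <- summarize_cohort(empty)
  expect_equal(nrow(s0), 0)
  expect_true(all(c("vaccine", "age_mean", "antipyretic_pct") %in%
                    names(s0)))

  one <- make_small_records(1)
  s1 <- summarize_cohort(one)
  expect_equal(s1$n_records, c(1, 1))  # vaccine row + total row
  expect_equal(s1$readings_mean, c(5, 5))
  expect_equal(s1$age_sd, c(0, 0))     # singleton SD reported as 0-width
})

test_that("summary sex fraction tracks the programmed 60% male share", {
  co <- simulate_cohort(2000, seed = 37)
  fr <- apply_cascade(co$readings, co$events, co$doses,
                      fever_config(min_records_per_vaccine = 1))
  s <- summarize_cohort(fr)
  tot <- s[s$vaccine == "Total", ]
  expect_equal(tot$male_pct, 60, tolerance = 0.05)  # within 3 points
})
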