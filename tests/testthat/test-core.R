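test_that("wear fraction is worn minutes over window minutes", {
  date <- as.Date("2021-02-01")
  start <- day_start(date)
  end <- start + 86400

  full <- make_day_minutes("s1", date, worn = 1:1440)
  expect_equal(compute_wear_fraction(full, start, end), 1.0)

  half <- make_day_minutes("s1", date, worn = 1:720)
  expect_equal(compute_wear_fraction(half, start, end), 0.5)

  # a 24-hour window has a denominator of exactly 1440 minutes: one worn
  # minute contributes 1/1440
  one <- make_day_minutes("s1", date, worn = 1L)
  expect_equal(compute_wear_fraction(one, start, end), 1 / 1440)

  expect_error(compute_wear_fraction(full, start, start), "at least one")
})

test_that("wear fraction equals a naive per-minute loop on random fixtures", {
  withr::local_seed(101)
  date <- as.Date("2021-02-03")
  start <- day_start(date)
  end <- start + 86400
  for (i in 1:25) {
    worn <- runif(1440) < runif(1)
    m <- make_day_minutes("s1", date, worn)
    # independent oracle: loop over each minute of the window and count
    naive <- 0L
    for (k in 0:1439) {
      ts <- start + 60 * k
      row <- which(m$timestamp == ts)
      if (length(row) == 1L && !is.na(m$heart_rate[row])) naive <- naive + 1L
    }
    expect_equal(compute_wear_fraction(m, start, end), naive / 1440)
  }
})

test_that("day summaries aggregate wear, steps, and heart rate", {
  date <- as.Date("2021-02-05")
  m <- make_day_minutes("s1", date, worn = 1:1440,
                        steps = rep(5, 1440), hr = 70)
  cohort <- wt_cohort(m)
  s <- summarize_days(cohort)
  expect_equal(nrow(s), 1L)
  expect_equal(s$wear_minutes, 1440L)
  expect_equal(s$wear_fraction, 1.0)
  expect_equal(s$total_steps, 7200L)
  expect_equal(s$mean_hr, 70)
  expect_true(s$valid_none && s$valid_stepcount1000 && s$valid_weartime80)
})

test_that("record-free study days are kept as 0-wear days, valid only under none", {
  date <- as.Date("2021-02-08")
  m <- make_day_minutes("s1", date, worn = 1:100, steps = rep(20, 1440))
  subjects <- tibble::tibble(subject_id = "s1", group = "g1",
                             study_start = date, study_end = date + 1)
  s <- summarize_days(wt_cohort(m, subjects))
  empty <- s[s$date == date + 1, ]
  expect_equal(empty$wear_minutes, 0L)
  expect_equal(empty$total_steps, 0L)
  expect_true(is.na(empty$mean_hr))
  expect_true(empty$valid_none)
  expect_false(empty$valid_stepcount1000 || empty$valid_weartime80)
  # and the inclusion of empty days is configurable
  s2 <- summarize_days(wt_cohort(m, subjects), include_empty_days = FALSE)
  expect_equal(nrow(s2), 1L)
})

test_that("steps in minutes without heart rate count toward totals, not wear", {
  date <- as.Date("2021-02-09")
  steps <- integer(1440); steps[200:209] <- 50L
  m <- make_day_minutes("s1", date, worn = 1:100, steps = steps)
  s <- summarize_days(wt_cohort(m))
  expect_equal(s$wear_minutes, 100L)
  expect_equal(s$total_steps, 500L)
  s2 <- summarize_days(wt_cohort(m), count_steps_without_hr = FALSE)
  expect_equal(s2$total_steps, 0L)
})

test_that("valid-day predicates use strict inequalities", {
  rules <- default_rules()
  at_1000 <- make_summary(total_steps = 1000)
  above <- make_summary(total_steps = 1001)
  expect_false(classify_valid_day(at_1000, rules$stepcount1000))
  expect_true(classify_valid_day(above, rules$stepcount1000))

  at_80 <- make_summary(wear_minutes = 1152)  # exactly 80%
  above_80 <- make_summary(wear_minutes = 1153)
  expect_false(classify_valid_day(at_80, rules$weartime80))
  expect_true(classify_valid_day(above_80, rules$weartime80))

  worst <- make_summary(wear_minutes = 0, total_steps = 0)
  expect_true(classify_valid_day(worst, rules$none))
})

test_that("a day can satisfy one rule and fail the other", {
  s <- make_summary(wear_minutes = round(0.81 * 1440), total_steps = 900)
  expect_true(classify_valid_day(s, default_rules()$weartime80))
  expect_false(classify_valid_day(s, default_rules()$stepcount1000))
})

test_that("subject estimates average over valid days only", {
  s <- add_validity(dplyr::bind_rows(
    make_summary(date = as.Date("2021-03-01"), total_steps = 8000),
    make_summary(date = as.Date("2021-03-02"), total_steps = 10000)
  ))
  est <- estimate_subjects(s, default_rules("none"))
  expect_equal(est$avg_daily_steps, 9000)
  expect_equal(est$n_valid_days, 2L)

  # zero valid days -> retained with absent estimates
  low <- add_validity(make_summary(wear_minutes = 10, total_steps = 3,
                                   mean_hr = 60))
  est_w <- estimate_subjects(low, default_rules("weartime80"))
  expect_equal(est_w$n_valid_days, 0L)
  expect_true(is.na(est_w$avg_daily_steps))
  expect_true(is.na(est_w$avg_daily_hr))
})

test_that("estimates match a brute-force filter-then-average oracle", {
  # 3-day toy: one day fails weartime80
  s <- add_validity(dplyr::bind_rows(
    make_summary(date = as.Date("2021-03-01"), wear_minutes = 1440,
                 total_steps = 9000, mean_hr = 72),
    make_summary(date = as.Date("2021-03-02"), wear_minutes = 700,
                 total_steps = 2000, mean_hr = 80),
    make_summary(date = as.Date("2021-03-03"), wear_minutes = 1300,
                 total_steps = 7000, mean_hr = 68)
  ))
  est <- estimate_subjects(s, default_rules("weartime80"))
  keep <- s$wear_fraction > 0.8  # oracle: filter then average
  expect_equal(est$avg_daily_steps, mean(s$total_steps[keep]))
  expect_equal(est$avg_daily_hr, mean(s$mean_hr[keep]))
  expect_equal(est$n_valid_days, sum(keep))
})

test_that("raising thresholds never adds valid days; stricter sets nest", {
  withr::local_seed(202)
  for (i in 1:20) {
    s <- dplyr::bind_rows(lapply(1:10, function(d) {
      make_summary(date = as.Date("2021-03-01") + d,
                   wear_minutes = sample(0:1440, 1),
                   total_steps = sample(0:15000, 1))
    }))
    floors <- sort(runif(2))
    steps_floors <- sort(sample(0:5000, 2))
    loose <- classify_valid_day(s, valid_day_rule("a", steps_floors[1],
                                                  floors[1]))
    strict <- classify_valid_day(s, valid_day_rule("b", steps_floors[2],
                                                   floors[2]))
    expect_true(all(!strict | loose))  # strict set nested in loose set
    expect_lte(sum(strict), sum(loose))
    # every preset nests in `none`
    for (rule in default_rules()) {
      expect_true(all(!classify_valid_day(s, rule) |
                        classify_valid_day(s, default_rules()$none)))
    }
  }
})

test_that("full compliance makes all three presets agree exactly", {
  cohort <- full_wear_cohort(n_subjects = 2, n_days = 4, steps_per_min = 2)
  s <- summarize_days(cohort)
  est <- estimate_subjects(s)
  wide <- split(est, est$rule)
  for (other in c("stepcount1000", "weartime80")) {
    expect_equal(wide[[other]]$avg_daily_steps, wide$none$avg_daily_steps)
    expect_equal(wide[[other]]$avg_daily_hr, wide$none$avg_daily_hr)
    expect_equal(wide[[other]]$n_valid_days, wide$none$n_valid_days)
  }
})

test_that("monthly trend recovers a geometric wear decay", {
  # wear 0.9, 0.81, 0.729 across three 30-day blocks -> changes -10%, -10%
  start <- as.Date("2021-04-01")
  block_wear <- c(0.9, 0.81, 0.729)
  m <- dplyr::bind_rows(lapply(0:89, function(d) {
    frac <- block_wear[d %/% 30 + 1]
    make_day_minutes("s1", start + d, worn = seq_len(round(frac * 1440)))
  }))
  subjects <- tibble::tibble(subject_id = "s1", group = "g1",
                             study_start = start, study_end = start + 89)
  s <- summarize_days(wt_cohort(m, subjects))
  tr <- monthly_wear_trend(s, subjects)
  expect_equal(tr$month, 1:3)
  expect_equal(tr$mean_wear_fraction, block_wear, tolerance = 1e-3)
  expect_equal(tr$rel_change[2:3], c(-0.1, -0.1), tolerance = 1e-2)
  expect_true(is.na(tr$rel_change[1]))
})

test_that("constant wear gives zero monthly change; short series give one block", {
  start <- as.Date("2021-04-01")
  m <- dplyr::bind_rows(lapply(0:59, function(d) {
    make_day_minutes("s1", start + d, worn = 1:720)
  }))
  subjects <- tibble::tibble(subject_id = "s1", group = "g1",
                             study_start = start, study_end = start + 59)
  tr <- monthly_wear_trend(summarize_days(wt_cohort(m, subjects)), subjects)
  expect_equal(tr$rel_change[2], 0)

  short <- dplyr::bind_rows(lapply(0:9, function(d) {
    make_day_minutes("s1", start + d, worn = 1:720)
  }))
  subjects_short <- tibble::tibble(subject_id = "s1", group = "g1",
                                   study_start = start,
                                   study_end = start + 9)
  tr_short <- monthly_wear_trend(summarize_days(wt_cohort(short,
                                                          subjects_short)),
                                 subjects_short)
  expect_equal(nrow(tr_short), 1L)
  expect_true(is.na(tr_short$rel_change))
})
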