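test_that("a 24-hour wear target with no decay yields full wear", {
  cfg <- full_wear_config(n_subjects = 1, study_days = 30)
  g <- generate_subject(cfg, "s1", seed = 1)
  expect_equal(nrow(g$minutes), 30 * 1440)
  expect_true(all(!is.na(g$minutes$heart_rate)))
  s <- summarize_days(wt_cohort(g$minutes, g$subject))
  expect_true(all(s$wear_fraction == 1))
})

test_that("never-wear subjects contribute zero records but stay in the cohort", {
  cfg <- synthetic_group_config("ghost", n_subjects = 2, study_days = 30,
                                never_wear_prob = 1)
  sim <- generate_cohort(cfg, master_seed = 3)
  expect_equal(nrow(sim$cohort$minutes), 0L)
  expect_equal(nrow(sim$cohort$subjects), 2L)
  expect_true(all(sim$truth$never_wear))
  # such subjects still contribute 0-step days under the no-threshold rule
  s <- summarize_days(sim$cohort)
  expect_true(all(s$valid_none))
  expect_true(all(s$wear_minutes == 0))
})

test_that("heart rate is registered exactly in worn minutes by construction", {
  cfg <- synthetic_group_config("half", n_subjects = 2, study_days = 30,
                                wear_hours = 12)
  sim <- generate_cohort(cfg, master_seed = 9)
  # emitted records are the worn minutes, so every record has a heart rate
  expect_true(all(!is.na(sim$cohort$minutes$heart_rate)))
  expect_true(all(sim$cohort$minutes$heart_rate >= 25 &
                    sim$cohort$minutes$heart_rate <= 250))
  expect_true(all(sim$cohort$minutes$steps >= 0 &
                    sim$cohort$minutes$steps <= 300))
})

test_that("mean daily steps match the closed-form bout arithmetic", {
  # expected steps/day = bouts * mean length * mean cadence + background
  cfg <- synthetic_group_config("calib", n_subjects = 60, study_days = 30,
                                bouts_per_day = 4, bout_length_mean = 10,
                                cadence_mean = 105,
                                background_step_rate = 4)
  sim <- generate_cohort(cfg, master_seed = 17)
  expected <- 4 * 10 * 105 + 4 * 15 * 60  # walking + waking-hour background
  observed <- mean(sim$truth$true_daily_steps)
  # Monte-Carlo tolerance: bout overlap trims a little, so allow a few %
  expect_equal(observed, expected, tolerance = 0.05)
})

test_that("identical master seeds reproduce the cohort byte for byte", {
  cfg <- synthetic_group_config("det", n_subjects = 2, study_days = 30,
                                wear_hours = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_cohort(cfg, master_seed = 21, dir = d1)
  generate_cohort(cfg, master_seed = 21, dir = d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "minutes.csv"))),
                   unname(tools::md5sum(file.path(d2, "minutes.csv"))))
  expect_identical(unname(tools::md5sum(file.path(d1, "truth.csv"))),
                   unname(tools::md5sum(file.path(d2, "truth.csv"))))
  # different seed, different cohort
  d3 <- withr::local_tempdir()
  generate_cohort(cfg, master_seed = 22, dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "minutes.csv"))),
                         unname(tools::md5sum(file.path(d3, "minutes.csv")))))
})

test_that("subjects are regenerable in isolation from the derived stream", {
  cfg <- synthetic_group_config("iso", n_subjects = 3, study_days = 30,
                                wear_hours = 14)
  sim <- generate_cohort(cfg, master_seed = 100)
  # regenerate subject 2 alone with its derived seed
  g2 <- generate_subject(cfg, "iso_002", weartime:::derive_seed(100, 2L))
  expect_equal(g2$minutes,
               sim$cohort$minutes[sim$cohort$minutes$subject_id == "iso_002",
                                  ])
  expect_equal(g2$truth, sim$truth[sim$truth$subject_id == "iso_002", ])
})

test_that("group-mean wear follows the configured ordering", {
  configs <- list(
    synthetic_group_config("high", n_subjects = 5, study_days = 30,
                           wear_hours = 20.8),
    synthetic_group_config("low", n_subjects = 5, study_days = 30,
                           wear_hours = 9.8)
  )
  sim <- generate_cohort(configs, master_seed = 31)
  s <- summarize_days(sim$cohort)
  mean_wear <- tapply(s$wear_fraction, s$group, mean)
  expect_gt(mean_wear[["high"]], mean_wear[["low"]])
  expect_equal(mean_wear[["high"]] * 24, 20.8, tolerance = 0.1)
})

test_that("a geometric monthly decay shows up in the wear trend", {
  cfg <- synthetic_group_config("fade", n_subjects = 10, study_days = 90,
                                wear_hours = 14, wear_hours_sd_subject = 1,
                                wear_hours_sd_day = 1, monthly_decay = 0.19)
  sim <- generate_cohort(cfg, master_seed = 41)
  s <- summarize_days(sim$cohort)
  tr <- monthly_wear_trend(s, sim$cohort$subjects)
  mean_change <- mean(tr$rel_change, na.rm = TRUE)
  expect_equal(mean_change, -0.19, tolerance = 0.05)
})

test_that("configuration validation rejects degenerate setups", {
  expect_error(synthetic_group_config("x", n_subjects = 1, study_days = 10),
               "study_days")
  expect_error(synthetic_group_config("x", 1, wear_hours = 25), "wear_hours")
  cfg <- synthetic_group_config("dup", 1)
  expect_error(generate_cohort(list(cfg, cfg), master_seed = 1),
               "duplicate group names")
  expect_error(generate_cohort(list(), master_seed = 1), "length")
})

test_that("recovery score is zero when estimates equal truth", {
  truth <- tibble::tibble(subject_id = c("a", "b"),
                          true_daily_steps = c(8000, 6000),
                          true_walking_hr = c(100, 110))
  est <- tibble::tibble(subject_id = c("a", "b"), group = "g",
                        rule = "none", n_valid_days = 10L,
                        avg_daily_steps = c(8000, 6000),
                        avg_daily_hr = c(70, 75))
  sc <- recovery_score(est, truth)
  expect_equal(sc$steps$mean_bias, 0)
  expect_equal(sc$steps$rmse, 0)
  expect_error(
    recovery_score(dplyr::mutate(est, subject_id = c("a", "zz")), truth),
    "absent from truth")
})

test_that("missing-at-random wear with high compliance leaves steps unbiased", {
  # coupling 0 and near-full wear: the unworn minutes miss steps at random,
  # so the no-threshold estimate sits close to the full-wear truth
  cfg <- synthetic_group_config("mar", n_subjects = 15, study_days = 60,
                                wear_hours = 23, wear_hours_sd_subject = 0.3,
                                wear_hours_sd_day = 0.3, monthly_decay = 0,
                                wear_activity_coupling = 0)
  sim <- generate_cohort(cfg, master_seed = 51)
  est <- estimate_subjects(summarize_days(sim$cohort), default_rules("none"))
  sc <- recovery_score(est, sim$truth)
  # bias bounded by the ~4% expected unworn share of steps
  expect_lt(abs(sc$steps$mean_bias) / mean(sim$truth$true_daily_steps), 0.06)
})

test_that("the six-group study configuration spans the compliance range", {
  configs <- study_group_configs()
  expect_equal(length(configs), 6L)
  hours <- vapply(configs, `[[`, numeric(1), "wear_hours")
  expect_equal(names(which.max(hours)), "hct_caregivers")
  expect_equal(names(which.min(hours)), "ped_onc_patients")
  decays <- vapply(configs, `[[`, numeric(1), "monthly_decay")
  expect_equal(range(decays), c(0.08, 0.19))
  days <- vapply(configs, `[[`, numeric(1), "study_days")
  expect_setequal(unique(days), c(90, 120))
  scaled <- study_group_configs(n_subjects = 4)
  expect_true(all(vapply(scaled, `[[`, numeric(1), "n_subjects") == 4))
})
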