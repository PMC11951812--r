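# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

day_start <- function(date) {
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
}

# Minute records for one subject-day: `worn` is a logical (or index) vector
# over the 1440 minutes of the day; steps likewise per minute. Minutes that
# are neither worn nor stepping get no row.
make_day_minutes <- function(subject_id, date, worn, steps = NULL,
                             hr = 70, group = "g1") {
  worn_idx <- if (is.logical(worn)) which(worn) else worn
  if (is.null(steps)) steps <- integer(1440)
  step_idx <- which(steps > 0)
  rows <- sort(union(worn_idx, step_idx))
  if (length(rows) == 0L) {
    return(tibble::tibble(subject_id = character(), group = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          heart_rate = numeric(), steps = integer()))
  }
  hr_vec <- rep(NA_real_, 1440)
  hr_vec[worn_idx] <- hr
  st_vec <- rep(NA_integer_, 1440)
  st_vec[rows] <- as.integer(steps[rows])
  tibble::tibble(
    subject_id = subject_id, group = group,
    timestamp = day_start(date) + 60 * (rows - 1L),
    heart_rate = hr_vec[rows], steps = st_vec[rows]
  )
}

# A small cohort where every subject wears the device every minute and takes
# `steps_per_min` steps per minute across `n_days` days.
full_wear_cohort <- function(n_subjects = 2, n_days = 3, steps_per_min = 5,
                             hr = 70, group = "g1",
                             start = as.Date("2021-03-01")) {
  minutes <- dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    dplyr::bind_rows(lapply(seq_len(n_days) - 1L, function(d) {
      make_day_minutes(sprintf("s%02d", i), start + d, worn = 1:1440,
                       steps = rep(steps_per_min, 1440), hr = hr,
                       group = group)
    }))
  }))
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n_subjects)), group = group,
    study_start = start, study_end = start + n_days - 1L
  )
  wt_cohort(minutes, subjects)
}

# Random sparse minute records for property tests: each of `n_days` days
# gets a random set of worn minutes and random step counts.
random_minutes <- function(subject_id = "r1", n_days = 3,
                           start = as.Date("2021-05-01"), group = "g1") {
  dplyr::bind_rows(lapply(seq_len(n_days) - 1L, function(d) {
    worn <- runif(1440) < runif(1, 0.1, 0.95)
    steps <- integer(1440)
    stepping <- runif(1440) < 0.3
    steps[stepping] <- rpois(sum(stepping), 40)
    make_day_minutes(subject_id, start + d, worn, steps = pmin(steps, 300L),
                     hr = round(runif(1, 55, 90)), group = group)
  }))
}

# Day-summary rows built directly (bypassing minute records) for rule tests.
make_summary <- function(subject_id = "s1", group = "g1",
                         date = as.Date("2021-03-01"),
                         wear_minutes = 1440, total_steps = 5000,
                         mean_hr = 70) {
  tibble::tibble(
    subject_id = subject_id, group = group, date = date,
    wear_minutes = as.integer(wear_minutes),
    wear_fraction = wear_minutes / 1440,
    total_steps = as.integer(total_steps),
    mean_hr = ifelse(wear_minutes > 0, mean_hr, NA_real_)
  )
}

add_validity <- function(summaries, rules = default_rules()) {
  for (rule in rules) {
    summaries[[paste0("valid_", rule$name)]] <-
      classify_valid_day(summaries, rule)
  }
  summaries
}

# A fast fully-compliant simulation config (no decay, full wear).
full_wear_config <- function(name = "full", n_subjects = 3,
                             study_days = 30) {
  synthetic_group_config(
    name, n_subjects = n_subjects, study_days = study_days,
    wear_hours = 24, wear_hours_sd_subject = 0, wear_hours_sd_day = 0,
    monthly_decay = 0, never_wear_prob = 0
  )
}
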