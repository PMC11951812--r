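#' Default diurnal wear-probability profile
#'
#' Relative propensity to wear the device in each hour of the day (24
#' weights, hour 0 first). The default is low overnight and flat during the
#' day, so partial wearers look like daytime-only wearers rather than
#' uniformly thinned ones.
#'
#' @return Numeric vector of 24 positive weights.
#' @export
default_diurnal_profile <- function() {
  w <- rep(1, 24)
  w[1:6] <- 0.35   # midnight - 6 am
  w[7] <- 0.7      # waking up
  w[23:24] <- 0.6  # late evening
  w
}

#' Configuration of one synthetic group
#'
#' Parameters of the minute-level generator for one group of subjects. The
#' generator draws, for each subject, a daily wear-time target (hours) that
#' decays geometrically by 30-day block (device abandonment), spreads it over
#' the day according to a diurnal profile, registers a heart rate in exactly
#' the worn minutes, plants Poisson-many walking bouts per day with normal
#' cadence, adds a background step rate in waking hours, and models heart
#' rate as a subject resting baseline plus minute-level baseline variation,
#' a fixed walking elevation in bout minutes, and measurement noise. Steps
#' are observed only in worn minutes; the pre-masking step totals are kept as
#' ground truth.
#'
#' @param name Group label.
#' @param n_subjects Subjects in the group.
#' @param study_days Study length in days (>= 30; typical designs use 90 or
#'   120).
#' @param wear_hours Group-level base daily wear target, hours in `[0, 24]`.
#' @param wear_hours_sd_subject Between-subject SD of the base target
#'   (hours).
#' @param wear_hours_sd_day Day-to-day SD of the daily target (hours); this
#'   is what occasionally lifts a low-compliance subject above an 80%-wear
#'   day, as real wear records do.
#' @param diurnal_profile 24 positive hourly weights.
#' @param monthly_decay Fractional drop of the wear target per 30-day block,
#'   in `[0, 1)`.
#' @param never_wear_prob Probability a subject never wears the device at
#'   all (received it but contributes zero records).
#' @param bouts_per_day Poisson mean of walking bouts per day.
#' @param bout_length_mean Mean bout length in minutes (`1 + Poisson`).
#' @param cadence_mean,cadence_sd Normal cadence (steps/min) in bout
#'   minutes, truncated at 1 and capped at 300.
#' @param background_step_rate Poisson mean of non-walking steps per waking
#'   minute (07:00-22:00).
#' @param resting_hr_mean,resting_hr_sd_subject Population mean and
#'   between-subject SD of resting heart rate (bpm).
#' @param resting_hr_sd_minute Minute-level SD of the baseline heart rate
#'   around the subject's resting level (bpm).
#' @param walking_hr_elevation_mean,walking_hr_elevation_sd Mean and
#'   between-subject SD of the heart-rate elevation in walking minutes
#'   (bpm).
#' @param hr_noise_sd Measurement noise SD on each registered heart rate
#'   (bpm).
#' @param wear_activity_coupling Coupling of wear to activity: during bout
#'   minutes the wear probability is multiplied by `1 + coupling` (capped at
#'   1). 0 means wear is missing-at-random with respect to activity.
#' @return An object of class `wt_sim_config`.
#' @export
synthetic_group_config <- function(name,
                                   n_subjects,
                                   study_days = 90,
                                   wear_hours = 16,
                                   wear_hours_sd_subject = 3,
                                   wear_hours_sd_day = 3.5,
                                   diurnal_profile = default_diurnal_profile(),
                                   monthly_decay = 0.1,
                                   never_wear_prob = 0,
                                   bouts_per_day = 4,
                                   bout_length_mean = 10,
                                   cadence_mean = 105,
                                   cadence_sd = 12,
                                   background_step_rate = 4,
                                   resting_hr_mean = 65,
                                   resting_hr_sd_subject = 6,
                                   resting_hr_sd_minute = 12,
                                   walking_hr_elevation_mean = 40,
                                   walking_hr_elevation_sd = 6,
                                   hr_noise_sd = 10,
                                   wear_activity_coupling = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            n_subjects >= 1, study_days >= 30,
            wear_hours >= 0, wear_hours <= 24,
            length(diurnal_profile) == 24, all(diurnal_profile > 0),
            monthly_decay >= 0, monthly_decay < 1,
            never_wear_prob >= 0, never_wear_prob <= 1,
            bouts_per_day >= 0, bout_length_mean >= 1,
            cadence_mean > 0, cadence_sd >= 0,
            background_step_rate >= 0, hr_noise_sd >= 0,
            wear_activity_coupling >= 0)
  structure(as.list(environment()), class = "wt_sim_config")
}

#' Synthetic analogues of a six-group wearables study
#'
#' A set of group configurations spanning the compliance range reported for
#' diverse wearable cohorts: base daily wear targets from 20.8 h (highly
#' compliant caregivers) down to 9.8 h (pediatric oncology patients),
#' monthly abandonment decay from 8% to 19%, never-worn devices in the
#' student and pediatric groups, and 120-day windows for the pediatric
#' groups versus 90 days elsewhere.
#'
#' @param n_subjects Optional named or unnamed integer vector of group sizes
#'   overriding the defaults (useful for scaled-down simulations); recycled
#'   as a single value.
#' @return Named list of [synthetic_group_config()] objects.
#' @export
study_group_configs <- function(n_subjects = NULL) {
  # wear_hours is the initial (first-block) target; bases are set so that
  # after monthly decay and never-worn devices the realized study-average
  # daily wear spans roughly 20.8 h down to 9.8 h across groups
  base <- list(
    synthetic_group_config("hct_caregivers", 30, 90, wear_hours = 23.5,
                           monthly_decay = 0.08),
    synthetic_group_config("hd_caregivers", 21, 90, wear_hours = 22.3,
                           monthly_decay = 0.10),
    synthetic_group_config("sci_caregivers", 19, 90, wear_hours = 21.3,
                           monthly_decay = 0.12),
    synthetic_group_config("students", 2107, 90, wear_hours = 17.3,
                           monthly_decay = 0.12, never_wear_prob = 0.03),
    synthetic_group_config("ped_onc_caregivers", 49, 120, wear_hours = 14.9,
                           monthly_decay = 0.10, never_wear_prob = 0.04),
    synthetic_group_config("ped_onc_patients", 44, 120, wear_hours = 13.9,
                           monthly_decay = 0.19, never_wear_prob = 0.05)
  )
  names(base) <- vapply(base, `[[`, character(1), "name")
  if (!is.null(n_subjects)) {
    n_subjects <- round(n_subjects)
    if (length(n_subjects) == 1L) {
      n_subjects <- rep(n_subjects, length(base))
    }
    stopifnot(length(n_subjects) == length(base), all(n_subjects >= 1))
    if (!is.null(names(n_subjects))) {
      stopifnot(all(names(n_subjects) %in% names(base)))
      for (nm in names(n_subjects)) base[[nm]]$n_subjects <- n_subjects[[nm]]
    } else {
      for (i in seq_along(base)) base[[i]]$n_subjects <- n_subjects[[i]]
    }
  }
  base
}

# Scale factor c such that sum_h 60 * min(1, c * w_h) equals the target
# minutes; the per-minute wear probability is then min(1, c * w_hour).
diurnal_scale <- function(weights, target_minutes) {
  if (target_minutes <= 0) return(0)
  achievable <- 60 * sum(weights > 0)
  if (target_minutes >= achievable) return(1 / min(weights[weights > 0]))
  f <- function(c) sum(60 * pmin(1, c * weights)) - target_minutes
  stats::uniroot(f, lower = 0, upper = 1 / min(weights[weights > 0]),
                 tol = 1e-10)$root
}

#' Generate one synthetic subject
#'
#' Simulates a full study of minute records for one subject under a group
#' configuration, together with the ground truth needed to score downstream
#' estimates: the subject's true mean daily step count under full wear (mean
#' over study days of all generated steps, observed or not), true walking
#' heart rate (resting level plus walking elevation), resting heart rate,
#' and the wear parameters actually drawn.
#'
#' @param config A [synthetic_group_config()].
#' @param subject_id Subject identifier.
#' @param seed Integer seed for this subject's private random stream.
#' @param start_date Date of study day 1.
#' @return List with elements `minutes` (observed records: worn minutes
#'   only, since an unworn device registers neither heart rate nor steps),
#'   `subject` (one-row metadata tibble), and `truth` (one-row tibble).
#' @export
generate_subject <- function(config, subject_id, seed,
                             start_date = as.Date("2021-01-01")) {
  stopifnot(inherits(config, "wt_sim_config"))
  with_private_rng(seed, function() {
    d <- config$study_days
    n_min <- d * 1440L
    hour <- rep(0:1439, d) %/% 60L

    # subject-level draws
    base_hours <- min(24, max(0, stats::rnorm(1, config$wear_hours,
                                              config$wear_hours_sd_subject)))
    resting <- stats::rnorm(1, config$resting_hr_mean,
                            config$resting_hr_sd_subject)
    elevation <- stats::rnorm(1, config$walking_hr_elevation_mean,
                              config$walking_hr_elevation_sd)
    never_wear <- stats::runif(1) < config$never_wear_prob

    # walking bouts: Poisson-many per day, placed in waking hours
    n_bouts <- stats::rpois(d, config$bouts_per_day)
    walking <- logical(n_min)
    for (day in which(n_bouts > 0)) {
      starts <- sample(420:1319, n_bouts[day], replace = TRUE)
      lens <- 1L + stats::rpois(n_bouts[day], config$bout_length_mean - 1)
      for (b in seq_along(starts)) {
        idx <- (day - 1L) * 1440L + starts[b] +
          seq_len(min(lens[b], 1440L - starts[b])) - 1L
        walking[idx + 1L] <- TRUE
      }
    }

    # steps: cadence in bout minutes, Poisson background in waking minutes
    steps <- integer(n_min)
    waking <- hour >= 7 & hour < 22
    steps[waking] <- stats::rpois(sum(waking), config$background_step_rate)
    nw <- sum(walking)
    if (nw > 0) {
      cad <- round(stats::rnorm(nw, config$cadence_mean, config$cadence_sd))
      steps[walking] <- pmin(300L, pmax(1L, as.integer(cad)))
    }

    # wear probability: daily target (decayed per 30-day block, day noise)
    # spread over the diurnal profile
    block_of_day <- (seq_len(d) - 1L) %/% 30L
    day_noise <- stats::rnorm(d, 0, config$wear_hours_sd_day)
    target_hours <- pmin(24, pmax(0, base_hours *
                                    (1 - config$monthly_decay)^block_of_day +
                                    day_noise))
    p_wear <- numeric(n_min)
    for (day in seq_len(d)) {
      cc <- diurnal_scale(config$diurnal_profile, target_hours[day] * 60)
      rng <- ((day - 1L) * 1440L + 1L):(day * 1440L)
      p_wear[rng] <- pmin(1, cc * config$diurnal_profile[hour[rng] + 1L])
    }
    if (config$wear_activity_coupling > 0) {
      p_wear[walking] <- pmin(1, p_wear[walking] *
                                (1 + config$wear_activity_coupling))
    }
    worn <- if (never_wear) rep(FALSE, n_min) else
      stats::runif(n_min) < p_wear

    # heart rate registered in worn minutes only
    hr <- rep(NA_real_, n_min)
    n_worn <- sum(worn)
    if (n_worn > 0) {
      hr_val <- resting +
        stats::rnorm(n_worn, 0, config$resting_hr_sd_minute) +
        elevation * walking[worn] +
        stats::rnorm(n_worn, 0, config$hr_noise_sd)
      hr[worn] <- pmin(250, pmax(25, round(hr_val)))
    }

    timestamps <- as.POSIXct(as.numeric(as.POSIXct(
      paste(start_date, "00:00:00"), tz = "UTC")) +
        60 * (seq_len(n_min) - 1L), tz = "UTC", origin = "1970-01-01")

    minutes <- tibble::tibble(
      subject_id = subject_id, group = config$name,
      timestamp = timestamps[worn],
      heart_rate = hr[worn],
      steps = steps[worn]
    )
    true_daily_steps <- sum(steps) / d
    truth <- tibble::tibble(
      subject_id = subject_id, group = config$name,
      true_daily_steps = true_daily_steps,
      true_walking_hr = resting + elevation,
      resting_hr = resting,
      wear_hours_drawn = if (never_wear) 0 else base_hours,
      never_wear = never_wear
    )
    subject <- tibble::tibble(
      subject_id = subject_id, group = config$name,
      study_start = start_date, study_end = start_date + d - 1L
    )
    list(minutes = minutes, subject = subject, truth = truth)
  })
}

# Deterministic per-subject seed from a master seed and subject index
# (multiplicative-congruential step, kept below 2^31).
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 2147483647 * 48271 +
                index * 16807) %% 2147483629) + 1L
}

#' Generate a synthetic cohort
#'
#' Generates every subject of every configured group. All randomness flows
#' from the master seed: subject `i` (in global enumeration order) uses the
#' derived stream `derive_seed(master_seed, i)`, so the same master seed
#' reproduces the cohort byte-for-byte and any single subject can be
#' regenerated in isolation.
#'
#' @param configs Named list of [synthetic_group_config()] objects (names
#'   must be unique and non-empty).
#' @param master_seed Integer master seed.
#' @param dir Optional directory; when given, writes `minutes.csv` (the
#'   minute-record dialect) and `truth.csv` there.
#' @param start_date Date of study day 1, common to all subjects.
#' @return List with elements `cohort` (a [wt_cohort()]) and `truth` (one
#'   row per subject).
#' @export
generate_cohort <- function(configs, master_seed, dir = NULL,
                            start_date = as.Date("2021-01-01")) {
  if (inherits(configs, "wt_sim_config")) configs <- list(configs)
  stopifnot(is.list(configs), length(configs) >= 1L,
            all(vapply(configs, inherits, logical(1), "wt_sim_config")))
  group_names <- vapply(configs, `[[`, character(1), "name")
  if (anyDuplicated(group_names)) {
    stop("duplicate group names in configs", call. = FALSE)
  }

  minutes <- list(); subjects <- list(); truths <- list()
  idx <- 0L
  for (cfg in configs) {
    for (k in seq_len(cfg$n_subjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%03d", cfg$name, k)
      g <- generate_subject(cfg, sid, derive_seed(master_seed, idx),
                            start_date = start_date)
      minutes[[idx]] <- g$minutes
      subjects[[idx]] <- g$subject
      truths[[idx]] <- g$truth
    }
  }
  cohort <- wt_cohort(dplyr::bind_rows(minutes), dplyr::bind_rows(subjects))
  truth <- dplyr::bind_rows(truths)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_minute_csv(cohort, file.path(dir, "minutes.csv"))
    readr::write_csv(truth, file.path(dir, "truth.csv"), progress = FALSE)
  }
  list(cohort = cohort, truth = truth)
}

#' Score estimates against generator ground truth
#'
#' Bias and root-mean-square error of per-subject average-daily-step
#' estimates against the generator's full-wear truth, aggregated per rule,
#' and — when walking-heart-rate results are supplied — of the
#' walking-heart-rate estimate against the true walking heart rate.
#'
#' @param estimates Output of [estimate_subjects()].
#' @param truth Truth table from [generate_cohort()].
#' @param walking Optional output of [walking_hr_analysis()].
#' @return List with `steps_per_subject`, `steps` (per-rule `mean_bias`,
#'   `rmse`, `n` over subjects with an estimate), and `walking` (`NULL`
#'   unless `walking` was given).
#' @export
recovery_score <- function(estimates, truth, walking = NULL) {
  unknown <- setdiff(estimates$subject_id, truth$subject_id)
  if (length(unknown) > 0L) {
    stop("estimates contain subject(s) absent from truth: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  per_subject <- estimates |>
    dplyr::inner_join(truth[c("subject_id", "true_daily_steps")],
                      by = "subject_id") |>
    dplyr::mutate(bias = .data$avg_daily_steps - .data$true_daily_steps)
  steps <- per_subject |>
    dplyr::filter(!is.na(.data$bias)) |>
    dplyr::group_by(.data$rule) |>
    dplyr::summarise(mean_bias = mean(.data$bias),
                     rmse = sqrt(mean(.data$bias^2)),
                     n = dplyr::n(), .groups = "drop")
  walking_score <- NULL
  if (!is.null(walking)) {
    walking_score <- walking |>
      dplyr::inner_join(truth[c("subject_id", "true_walking_hr")],
                        by = "subject_id") |>
      dplyr::mutate(bias = .data$walking_hr_mean - .data$true_walking_hr) |>
      dplyr::filter(!is.na(.data$bias)) |>
      dplyr::summarise(mean_bias = mean(.data$bias),
                       rmse = sqrt(mean(.data$bias^2)),
                       n = dplyr::n())
  }
  list(steps_per_subject = per_subject, steps = steps,
       walking = walking_score)
}
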