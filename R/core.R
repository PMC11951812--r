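#' Wear fraction over a time window
#'
#' Wear time is proxied by the presence of a registered per-minute heart rate:
#' the device writes one heart-rate value per minute while worn, so
#' `wear fraction = (# minutes with a registered heart rate) / (total minutes
#' in the window)`. A 24-hour window always has 1440 total minutes.
#'
#' @param minutes Minute-record tibble for a single subject (columns
#'   `timestamp`, `heart_rate`; other columns are ignored).
#' @param window_start,window_end POSIXct bounds of the window;
#'   `window_start` inclusive, `window_end` exclusive.
#' @return Wear fraction in `[0, 1]`.
#' @export
#' @examples
#' start <- as.POSIXct("2021-01-01 00:00", tz = "UTC")
#' m <- tibble::tibble(
#'   timestamp = start + 60 * (0:719),
#'   heart_rate = 70
#' )
#' compute_wear_fraction(m, start, start + 86400)  # 720 / 1440 = 0.5
compute_wear_fraction <- function(minutes, window_start, window_end) {
  stopifnot(inherits(window_start, "POSIXct"), inherits(window_end, "POSIXct"))
  total_minutes <- as.numeric(difftime(window_end, window_start,
                                       units = "mins"))
  if (!is.finite(total_minutes) || total_minutes < 1) {
    stop("window must span at least one minute", call. = FALSE)
  }
  in_window <- minutes$timestamp >= window_start &
    minutes$timestamp < window_end
  worn <- sum(in_window & !is.na(minutes$heart_rate))
  worn / total_minutes
}

#' Summarise minute records into calendar-day summaries
#'
#' Aggregates each subject's minute records into one row per calendar day:
#' wear minutes (minutes with a registered heart rate), wear fraction
#' (`wear_minutes / 1440`; days are local midnight-to-midnight with a constant
#' 1440-minute denominator), registered step total, mean heart rate over worn
#' minutes (`NA` on days with zero wear), and one `valid_<rule>` flag per
#' supplied rule.
#'
#' Days of the study window with no records at all are included as 0-wear,
#' 0-step days by default: a participant who received a device but never wore
#' it still contributes days under a rule with no thresholds. Set
#' `include_empty_days = FALSE` to restrict output to days with at least one
#' record.
#'
#' Steps registered in minutes without a heart rate count toward the day's
#' step total (they were registered) but never toward wear minutes; set
#' `count_steps_without_hr = FALSE` to restrict step totals to worn minutes.
#'
#' @param cohort A [wt_cohort()].
#' @param rules A [valid_day_rule()] or list of them; defaults to the three
#'   presets from [default_rules()].
#' @param include_empty_days Include record-free study days as 0-wear days?
#' @param count_steps_without_hr Count steps from minutes lacking a heart
#'   rate?
#' @return Tibble with columns `subject_id`, `group`, `date`, `wear_minutes`,
#'   `wear_fraction`, `total_steps`, `mean_hr`, and `valid_<name>` per rule.
#' @export
summarize_days <- function(cohort, rules = default_rules(),
                           include_empty_days = TRUE,
                           count_steps_without_hr = TRUE) {
  stopifnot(inherits(cohort, "wt_cohort"))
  rules <- as_rule_list(rules)

  m <- cohort$minutes
  step_source <- if (count_steps_without_hr) {
    m$steps
  } else {
    ifelse(is.na(m$heart_rate), NA_integer_, m$steps)
  }
  observed <- m |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC"),
                  .steps = step_source) |>
    dplyr::group_by(.data$subject_id, .data$date) |>
    dplyr::summarise(
      wear_minutes = sum(!is.na(.data$heart_rate)),
      total_steps = sum(.data$.steps, na.rm = TRUE),
      mean_hr = if (any(!is.na(.data$heart_rate))) {
        mean(.data$heart_rate, na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  if (include_empty_days) {
    grid <- cohort$subjects |>
      dplyr::rowwise() |>
      dplyr::mutate(date = list(seq(.data$study_start, .data$study_end,
                                    by = "day"))) |>
      dplyr::ungroup() |>
      tidyr::unnest("date") |>
      dplyr::select("subject_id", "group", "date")
    out <- grid |>
      dplyr::left_join(observed, by = c("subject_id", "date")) |>
      tidyr::replace_na(list(wear_minutes = 0L, total_steps = 0L))
  } else {
    out <- observed |>
      dplyr::left_join(cohort$subjects[c("subject_id", "group")],
                       by = "subject_id") |>
      dplyr::relocate("group", .after = "subject_id")
  }

  out <- out |>
    dplyr::mutate(
      wear_minutes = as.integer(.data$wear_minutes),
      total_steps = as.integer(.data$total_steps),
      wear_fraction = .data$wear_minutes / 1440,
      .after = "wear_minutes"
    ) |>
    dplyr::arrange(.data$subject_id, .data$date)

  for (rule in rules) {
    out[[paste0("valid_", rule$name)]] <- classify_valid_day(out, rule)
  }
  out
}

#' Per-subject estimates under a valid-day rule
#'
#' For each subject, averages daily step totals and daily mean heart rates
#' over the days that are valid under each rule. The heart-rate estimate is a
#' mean of daily means (each valid day weighted equally), restricted to valid
#' days with nonzero wear. Subjects with no valid days are retained with
#' `NA` estimates and `n_valid_days = 0` rather than silently dropped.
#'
#' @param summaries Day-summary tibble from [summarize_days()]; must contain
#'   the `valid_<name>` column of every requested rule.
#' @param rules A [valid_day_rule()] or list of them.
#' @return Tibble with one row per subject and rule: `subject_id`, `group`,
#'   `rule`, `n_valid_days`, `avg_daily_steps`, `avg_daily_hr`.
#' @export
estimate_subjects <- function(summaries, rules = default_rules()) {
  rules <- as_rule_list(rules)
  missing_flags <- setdiff(paste0("valid_", names(rules)), names(summaries))
  if (length(missing_flags) > 0L) {
    stop("summaries lack validity column(s): ",
         paste(missing_flags, collapse = ", "),
         "; recompute with summarize_days()", call. = FALSE)
  }
  roster <- dplyr::distinct(summaries, .data$subject_id, .data$group)

  per_rule <- lapply(names(rules), function(rn) {
    flag <- summaries[[paste0("valid_", rn)]]
    summaries[flag, ] |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(
        n_valid_days = dplyr::n(),
        avg_daily_steps = mean(.data$total_steps),
        avg_daily_hr = if (any(!is.na(.data$mean_hr))) {
          mean(.data$mean_hr, na.rm = TRUE)
        } else {
          NA_real_
        },
        .groups = "drop"
      ) |>
      dplyr::right_join(roster, by = "subject_id") |>
      tidyr::replace_na(list(n_valid_days = 0L)) |>
      dplyr::mutate(rule = rn) |>
      dplyr::select("subject_id", "group", "rule", "n_valid_days",
                    "avg_daily_steps", "avg_daily_hr")
  })
  dplyr::bind_rows(per_rule) |>
    dplyr::arrange(.data$rule, .data$subject_id)
}

#' Monthly wear-time trend (wearables abandonment)
#'
#' Tracks average daily wear fraction across consecutive 30-day blocks of the
#' study ("months": study lengths of 90 and 120 days tile exactly into such
#' blocks) and the relative change between consecutive blocks, the usual
#' summary of progressive device abandonment.
#'
#' @param summaries Day-summary tibble from [summarize_days()] (with empty
#'   days included, so every study day contributes to its block).
#' @param subjects Subject metadata tibble (`subject_id`, `study_start`), e.g.
#'   the `subjects` element of a [wt_cohort()].
#' @param block_days Days per block; 30 by default.
#' @return Tibble with one row per subject and block: `subject_id`, `group`,
#'   `month` (1-based block index), `n_days`, `mean_wear_fraction`, and
#'   `rel_change` — `(mean_m - mean_{m-1}) / mean_{m-1}`, `NA` for the first
#'   block or when the previous block had zero wear.
#' @export
monthly_wear_trend <- function(summaries, subjects, block_days = 30) {
  stopifnot(block_days >= 1)
  out <- summaries |>
    dplyr::inner_join(subjects[c("subject_id", "study_start")],
                      by = "subject_id") |>
    dplyr::mutate(
      month = as.integer(as.numeric(.data$date - .data$study_start) %/%
                           block_days) + 1L
    ) |>
    dplyr::group_by(.data$subject_id, .data$group, .data$month) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean_wear_fraction = mean(.data$wear_fraction),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$subject_id, .data$month) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      rel_change = {
        prev <- dplyr::lag(.data$mean_wear_fraction)
        ifelse(is.na(prev) | prev == 0, NA_real_,
               (.data$mean_wear_fraction - prev) / prev)
      }
    ) |>
    dplyr::ungroup()
  out
}
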