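#' Population-level estimates per group and rule
#'
#' Group means of the per-subject estimates under each valid-day rule,
#' together with retention: how many subjects keep at least one valid day
#' (and therefore a defined estimate) under the rule. Population means are
#' unweighted means of subject estimates — each subject counts once however
#' many valid days it has.
#'
#' @param summaries Day-summary tibble from [summarize_days()].
#' @param rules A [valid_day_rule()] or list of them.
#' @return Tibble with one row per (group, rule): `n_subjects` (in the
#'   group), `n_retained` (subjects with >= 1 valid day), `retention`,
#'   `mean_n_valid_days`, `mean_avg_daily_steps`, `mean_avg_daily_hr` (group
#'   means over retained subjects; `NaN` when no subject is retained).
#' @export
population_estimates <- function(summaries, rules = default_rules()) {
  est <- estimate_subjects(summaries, rules)
  est |>
    dplyr::group_by(.data$group, .data$rule) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      n_retained = sum(.data$n_valid_days > 0),
      retention = .data$n_retained / .data$n_subjects,
      mean_n_valid_days = mean(.data$n_valid_days),
      mean_avg_daily_steps = mean(.data$avg_daily_steps, na.rm = TRUE),
      mean_avg_daily_hr = mean(.data$avg_daily_hr, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Individual differences between two valid-day rules
#'
#' Per-subject change of the average-daily-step and heart-rate estimates when
#' switching from `rule_a` to `rule_b`. The signed delta is
#' `estimate(rule_b) - estimate(rule_a)`. Subjects lacking an estimate under
#' either rule (no valid days) are retained with `NA` deltas and
#' `both_defined = FALSE`, so they can be reported rather than silently
#' dropped.
#'
#' @param summaries Day-summary tibble from [summarize_days()].
#' @param rule_a,rule_b [valid_day_rule()] objects (e.g. `none` and
#'   `weartime80`, the least and most stringent presets).
#' @return Tibble with one row per subject: estimates under both rules,
#'   `delta_steps`, `abs_delta_steps`, `delta_hr`, `abs_delta_hr`,
#'   `both_defined`.
#' @export
individual_differences <- function(summaries,
                                   rule_a = default_rules()$none,
                                   rule_b = default_rules()$weartime80) {
  stopifnot(inherits(rule_a, "wt_rule"), inherits(rule_b, "wt_rule"))
  est <- estimate_subjects(summaries, list(rule_a, rule_b))
  a <- est[est$rule == rule_a$name, ]
  b <- est[est$rule == rule_b$name, ]
  dplyr::inner_join(
    dplyr::rename(a[c("subject_id", "group", "n_valid_days",
                      "avg_daily_steps", "avg_daily_hr")],
                  n_valid_days_a = "n_valid_days",
                  steps_a = "avg_daily_steps", hr_a = "avg_daily_hr"),
    dplyr::rename(b[c("subject_id", "n_valid_days", "avg_daily_steps",
                      "avg_daily_hr")],
                  n_valid_days_b = "n_valid_days",
                  steps_b = "avg_daily_steps", hr_b = "avg_daily_hr"),
    by = "subject_id"
  ) |>
    dplyr::mutate(
      delta_steps = .data$steps_b - .data$steps_a,
      abs_delta_steps = abs(.data$delta_steps),
      delta_hr = .data$hr_b - .data$hr_a,
      abs_delta_hr = abs(.data$delta_hr),
      both_defined = .data$n_valid_days_a > 0 & .data$n_valid_days_b > 0
    )
}

#' Bin individual step-count differences
#'
#' Tallies subjects into bins of absolute average-daily-step difference
#' between two rules. The default edges follow the physical-activity-level
#' style grouping: `[0, 500)`, `[500, 1000)`, `[1000, 3000)`, `[3000, 5000)`,
#' `[5000, Inf)`. Only subjects with estimates under both rules enter the
#' bins; their fractions sum to one per group.
#'
#' @param diffs Output of [individual_differences()].
#' @param edges Increasing numeric bin edges, starting at 0; `Inf` is
#'   appended if absent.
#' @return Tibble with one row per (group, bin): `bin` (label), `count`,
#'   `fraction` (of the group's subjects with both estimates), plus
#'   `n_undefined` subjects excluded for lacking an estimate.
#' @export
bin_differences <- function(diffs,
                            edges = c(0, 500, 1000, 3000, 5000)) {
  stopifnot(is.numeric(edges), !is.unsorted(edges, strictly = TRUE),
            edges[1] == 0)
  if (!is.infinite(edges[length(edges)])) edges <- c(edges, Inf)
  labels <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")

  usable <- diffs[diffs$both_defined, ]
  usable$bin <- cut(usable$abs_delta_steps, breaks = edges, right = FALSE,
                    labels = labels, include.lowest = FALSE)
  undef <- diffs |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_undefined = sum(!.data$both_defined), .groups = "drop")

  usable |>
    dplyr::group_by(.data$group) |>
    dplyr::count(.data$bin, .drop = FALSE, name = "count") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::left_join(undef, by = "group")
}

#' Classify average daily step count into activity levels
#'
#' The standard daily-step activity categories: sedentary below 5000 steps,
#' low active 5000-7500, somewhat active 7500-10,000, highly active 10,000
#' and above. Bins are half-open on the right, so 7500 is "somewhat active"
#' and 10,000 is "highly active".
#'
#' @param avg_daily_steps Non-negative numeric vector (`NA` allowed).
#' @return Ordered factor with levels `sedentary < low active <
#'   somewhat active < highly active`.
#' @export
#' @examples
#' classify_activity_level(c(4800, 5000, 7500, 10000))
classify_activity_level <- function(avg_daily_steps) {
  if (any(avg_daily_steps < 0, na.rm = TRUE)) {
    stop("average daily steps must be non-negative", call. = FALSE)
  }
  cut(avg_daily_steps,
      breaks = c(0, 5000, 7500, 10000, Inf),
      labels = c("sedentary", "low active", "somewhat active",
                 "highly active"),
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Subjects whose activity category changes between rules
#'
#' Flags subjects whose activity-level classification (per
#' [classify_activity_level()]) differs when their average daily step count
#' is computed under `rule_a` versus `rule_b` — the misclassification an
#' unexamined valid-day definition can induce in, say, intervention targeting.
#'
#' @inheritParams individual_differences
#' @return Tibble of flagged subjects: `subject_id`, `group`, `steps_a`,
#'   `steps_b`, `category_a`, `category_b`. Empty when no subject changes
#'   category.
#' @export
misclassification_report <- function(summaries,
                                     rule_a = default_rules()$none,
                                     rule_b = default_rules()$weartime80) {
  diffs <- individual_differences(summaries, rule_a, rule_b)
  usable <- diffs[diffs$both_defined, ]
  usable$category_a <- classify_activity_level(usable$steps_a)
  usable$category_b <- classify_activity_level(usable$steps_b)
  usable[usable$category_a != usable$category_b,
         c("subject_id", "group", "steps_a", "steps_b",
           "category_a", "category_b")]
}
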