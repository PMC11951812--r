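#' Extract walking minutes by cadence threshold
#'
#' A minute whose registered step count reaches the cadence threshold
#' (default 80 steps/min) very likely belongs to a walking bout; the heart
#' rates registered in those minutes are the walking-heart-rate samples. By
#' default the threshold is inclusive (a minute totalling exactly 80 steps is
#' a walking minute); set `inclusive = FALSE` for a strict `>` cut, which
#' moves the boundary by one step. High-cadence minutes lacking a heart rate
#' contribute no sample; they are dropped and counted in the `n_missing_hr`
#' attribute (with a warning when any are dropped).
#'
#' @param minutes Minute-record tibble (possibly several subjects).
#' @param cadence_threshold Steps per minute marking likely walking; > 0.
#' @param inclusive Treat a minute with exactly `cadence_threshold` steps as
#'   walking?
#' @param warn Warn when high-cadence minutes without heart rate are dropped?
#' @return Tibble of walking samples (`subject_id`, `timestamp`,
#'   `heart_rate`, `steps`) with attributes `cadence_threshold` and
#'   `n_missing_hr`.
#' @export
extract_walking_minutes <- function(minutes, cadence_threshold = 80,
                                    inclusive = TRUE, warn = TRUE) {
  stopifnot(is.numeric(cadence_threshold), cadence_threshold > 0)
  st <- minutes$steps
  fast <- !is.na(st) &
    (if (inclusive) st >= cadence_threshold else st > cadence_threshold)
  no_hr <- fast & is.na(minutes$heart_rate)
  n_missing <- sum(no_hr)
  if (warn && n_missing > 0L) {
    warning(n_missing, " high-cadence minute(s) without a registered ",
            "heart rate dropped", call. = FALSE)
  }
  out <- minutes[fast & !no_hr,
                 intersect(c("subject_id", "timestamp", "heart_rate",
                             "steps"), names(minutes))]
  attr(out, "cadence_threshold") <- cadence_threshold
  attr(out, "n_missing_hr") <- n_missing
  out
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by the square root
#' of the sample size.
#'
#' @param x Numeric vector with at least two values.
#' @return Standard error in the units of `x`.
#' @export
#' @examples
#' standard_error(c(90, 110))  # 10 / sqrt(2)
standard_error <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) {
    stop("standard error requires at least 2 samples", call. = FALSE)
  }
  stats::sd(x) / sqrt(length(x))
}

# Run fn with a private RNG stream: seeds with `seed` when given, restores
# the caller's RNG state afterwards.
with_private_rng <- function(seed, fn) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  fn()
}

#' Standard-error convergence curve under random subsampling
#'
#' For each subsample size `n` in the grid, draws `repetitions` uniform
#' subsamples without replacement from the walking-heart-rate samples,
#' computes the standard error of each, and records the mean — the curve
#' whose crossing below a bpm threshold defines the minimum number of
#' samples needed for a confident walking-heart-rate estimate. Subsampling
#' ignores temporal order (wear time treated as random).
#'
#' @param hr Numeric vector of heart-rate samples (bpm).
#' @param n_grid Strictly increasing integer grid of subsample sizes; by
#'   default `seq(10, length(hr), by = 10)`. Must not exceed the sample
#'   count.
#' @param repetitions Subsamples per grid point.
#' @param seed Optional integer seed; when given, the curve is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Tibble with columns `n` and `mean_se`, plus attributes
#'   `repetitions` and `seed`.
#' @export
convergence_curve <- function(hr, n_grid = NULL, repetitions = 100,
                              seed = NULL) {
  hr <- hr[!is.na(hr)]
  total <- length(hr)
  if (is.null(n_grid)) {
    if (total < 10L) stop("need at least 10 samples for the default grid",
                          call. = FALSE)
    n_grid <- seq(10L, total, by = 10L)
  }
  n_grid <- as.integer(n_grid)
  stopifnot(length(n_grid) >= 1L, !is.unsorted(n_grid, strictly = TRUE),
            n_grid[1] >= 2L, repetitions >= 1)
  if (max(n_grid) > total) {
    stop("subsample grid exceeds the number of samples (", total, ")",
         call. = FALSE)
  }

  mean_se <- with_private_rng(seed, function() {
    vapply(n_grid, function(n) {
      # reps x n index matrix; column-wise moments avoid an sd() per draw
      idx <- vapply(seq_len(repetitions), function(i) sample.int(total, n),
                    integer(n))
      xs <- matrix(hr[idx], nrow = n)
      mu <- colMeans(xs)
      ss <- colSums(xs^2) - n * mu^2
      mean(sqrt(pmax(ss, 0) / (n - 1)) / sqrt(n))
    }, numeric(1))
  })
  out <- tibble::tibble(n = n_grid, mean_se = mean_se)
  attr(out, "repetitions") <- repetitions
  attr(out, "seed") <- seed
  out
}

#' Minimum sample count for standard-error convergence
#'
#' Smallest grid size at which the mean standard error is at or below the
#' threshold *and stays there for every larger grid size* (a sustained
#' crossing, so a single lucky subsample cannot declare convergence).
#'
#' @param trace Convergence curve from [convergence_curve()].
#' @param threshold Convergence threshold in bpm; 1 by default.
#' @return The converging sample count as an integer, or `NA_integer_` when
#'   the curve never sustains below the threshold.
#' @export
min_samples_for_convergence <- function(trace, threshold = 1) {
  stopifnot(nrow(trace) >= 1L, threshold > 0)
  below <- trace$mean_se <= threshold
  sustained <- rev(cumprod(rev(below))) == 1
  if (!any(sustained)) return(NA_integer_)
  as.integer(trace$n[which(sustained)[1]])
}

#' Days of data collection needed to accumulate walking samples
#'
#' Accumulates a subject's walking minutes in chronological study order and
#' reports the 1-based study-day index on which the cumulative count first
#' reaches the required number of samples.
#'
#' @param walking Walking-sample tibble for one subject (from
#'   [extract_walking_minutes()]).
#' @param study_start Date of the first study day.
#' @param n_required Required number of samples (>= 1).
#' @return Integer day index, or `NA_integer_` when the subject never
#'   accumulates that many samples.
#' @export
days_to_reach <- function(walking, study_start, n_required) {
  stopifnot(is.numeric(n_required), n_required >= 1)
  if (nrow(walking) < n_required) return(NA_integer_)
  ts <- sort(walking$timestamp)
  hit <- ts[ceiling(n_required)]
  as.integer(as.numeric(as.Date(hit, tz = "UTC") - as.Date(study_start))) + 1L
}

#' Per-subject walking-heart-rate analysis and feasibility
#'
#' Runs the full walking-heart-rate procedure for every subject of a cohort:
#' extract walking minutes by cadence, build the standard-error convergence
#' curve by random subsampling, find the minimum converged sample count, the
#' number of study days needed to accumulate it, and the walking-heart-rate
#' estimate (mean over all walking samples). Each subject is then labelled by
#' which research questions its data can answer: `both`, `steps_only`
#' (a valid-day step estimate exists but walking heart rate never converges),
#' `walking_only` (no valid day under the reference rule, yet enough walking
#' samples — the low-compliance subject whose data still answers a question),
#' or `neither`.
#'
#' @param cohort A [wt_cohort()].
#' @param summaries Day summaries from [summarize_days()]; computed on the
#'   fly when `NULL`.
#' @param reference_rule Valid-day rule defining "has a step estimate";
#'   the 80% wear-time rule by default.
#' @param cadence_threshold,inclusive Passed to
#'   [extract_walking_minutes()].
#' @param se_threshold Convergence threshold in bpm.
#' @param repetitions Subsamples per grid point.
#' @param grid_step Grid spacing for the convergence curve.
#' @param grid_cap Upper bound on the convergence grid; caps the quadratic
#'   subsampling cost for subjects with very many walking minutes. Since the
#'   mean standard error only falls beyond the cap, a sustained crossing
#'   within the capped grid is decisive.
#' @param seed Optional integer seed; per-subject streams are derived from
#'   it deterministically, so single subjects are regenerable in isolation.
#' @return Tibble with one row per subject: `subject_id`, `group`,
#'   `n_walking_minutes`, `n_required`, `converged`, `days_to_reach`,
#'   `walking_hr_mean`, `has_step_estimate`, `feasibility`.
#' @export
walking_hr_analysis <- function(cohort, summaries = NULL,
                                reference_rule = default_rules()$weartime80,
                                cadence_threshold = 80, inclusive = TRUE,
                                se_threshold = 1, repetitions = 100,
                                grid_step = 10, grid_cap = 1000,
                                seed = NULL) {
  stopifnot(inherits(cohort, "wt_cohort"), inherits(reference_rule, "wt_rule"))
  if (is.null(summaries)) {
    summaries <- summarize_days(cohort, list(reference_rule))
  }
  flag_col <- paste0("valid_", reference_rule$name)
  if (!flag_col %in% names(summaries)) {
    stop("summaries lack column ", flag_col, call. = FALSE)
  }
  step_ok <- summaries |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(has_step_estimate = any(.data[[flag_col]]),
                     .groups = "drop")

  walking_all <- extract_walking_minutes(cohort$minutes, cadence_threshold,
                                         inclusive, warn = FALSE)
  subjects <- cohort$subjects
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    sid <- subjects$subject_id[i]
    w <- walking_all[walking_all$subject_id == sid, ]
    n_w <- nrow(w)
    n_req <- NA_integer_
    days <- NA_integer_
    hr_mean <- if (n_w > 0L) mean(w$heart_rate) else NA_real_
    if (n_w >= max(2L, grid_step)) {
      grid <- seq(grid_step, min(n_w, grid_cap), by = grid_step)
      sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
      trace <- convergence_curve(w$heart_rate, n_grid = grid,
                                 repetitions = repetitions, seed = sub_seed)
      n_req <- min_samples_for_convergence(trace, se_threshold)
      if (!is.na(n_req)) {
        days <- days_to_reach(w, subjects$study_start[i], n_req)
      }
    }
    tibble::tibble(
      subject_id = sid, group = subjects$group[i],
      n_walking_minutes = n_w, n_required = n_req,
      converged = !is.na(n_req), days_to_reach = days,
      walking_hr_mean = hr_mean
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::left_join(step_ok, by = "subject_id")
  out$feasibility <- classify_feasibility(out$has_step_estimate,
                                          out$converged)
  out
}

#' Feasibility label from the two data-sufficiency booleans
#'
#' @param has_step_estimate Subject has >= 1 valid day under the reference
#'   rule.
#' @param has_walking_hr Subject's walking-heart-rate standard error
#'   converged.
#' @return Factor with levels `both`, `steps_only`, `walking_only`,
#'   `neither`.
#' @export
classify_feasibility <- function(has_step_estimate, has_walking_hr) {
  stopifnot(length(has_step_estimate) == length(has_walking_hr))
  lab <- dplyr::case_when(
    has_step_estimate & has_walking_hr ~ "both",
    has_step_estimate & !has_walking_hr ~ "steps_only",
    !has_step_estimate & has_walking_hr ~ "walking_only",
    TRUE ~ "neither"
  )
  factor(lab, levels = c("both", "steps_only", "walking_only", "neither"))
}
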