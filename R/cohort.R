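#' Construct a minute-level cohort
#'
#' Bundles minute records with per-subject study metadata. Minute records are
#' sparse: a subject-minute with no row means the device registered neither a
#' heart rate nor steps in that minute. Timestamps are timezone-naive local
#' device time, represented as POSIXct in `"UTC"` so that every calendar day
#' has exactly 1440 minutes (no daylight-saving transitions).
#'
#' @param minutes Tibble with columns `subject_id` (character), `group`
#'   (character), `timestamp` (POSIXct, whole minutes), `heart_rate` (numeric
#'   bpm, `NA` when the device was not worn), `steps` (integer, `NA` when no
#'   step count was registered).
#' @param subjects Tibble with columns `subject_id`, `group`, `study_start`,
#'   `study_end` (Dates, inclusive). When `NULL`, the study window of each
#'   subject is inferred as the span of its observed records.
#'
#' @return An object of class `wt_cohort`: a list with elements `minutes` and
#'   `subjects`.
#' @export
wt_cohort <- function(minutes, subjects = NULL) {
  minutes <- tibble::as_tibble(minutes)
  required <- c("subject_id", "group", "timestamp", "heart_rate", "steps")
  missing_cols <- setdiff(required, names(minutes))
  if (length(missing_cols) > 0L) {
    stop("minutes is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  minutes <- minutes[required]
  if (nrow(minutes) > 0L) {
    if (!inherits(minutes$timestamp, "POSIXct")) {
      stop("timestamp must be POSIXct", call. = FALSE)
    }
    secs <- as.numeric(minutes$timestamp)
    if (any(secs %% 60 != 0)) {
      stop("timestamps must fall on whole minutes", call. = FALSE)
    }
    hr <- minutes$heart_rate
    if (any(!is.na(hr) & (hr < 25 | hr > 250))) {
      stop("heart_rate values outside the plausible range [25, 250]",
           call. = FALSE)
    }
    st <- minutes$steps
    if (any(!is.na(st) & (st < 0 | st > 300))) {
      stop("per-minute steps outside the plausible range [0, 300]",
           call. = FALSE)
    }
    dup <- duplicated(minutes[c("subject_id", "timestamp")])
    if (any(dup)) {
      stop("duplicate subject-minute records (first at row ", which(dup)[1],
           ")", call. = FALSE)
    }
    minutes <- dplyr::arrange(minutes, .data$subject_id, .data$timestamp)
  }

  if (is.null(subjects)) {
    subjects <- minutes |>
      dplyr::group_by(.data$subject_id, .data$group) |>
      dplyr::summarise(
        study_start = as.Date(min(.data$timestamp), tz = "UTC"),
        study_end = as.Date(max(.data$timestamp), tz = "UTC"),
        .groups = "drop"
      )
  } else {
    subjects <- tibble::as_tibble(subjects)
    req <- c("subject_id", "group", "study_start", "study_end")
    if (!all(req %in% names(subjects))) {
      stop("subjects must have columns ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    subjects <- subjects[req]
    if (anyDuplicated(subjects$subject_id)) {
      stop("duplicate subject_id in subjects table", call. = FALSE)
    }
    if (any(subjects$study_end < subjects$study_start)) {
      stop("study_end before study_start", call. = FALSE)
    }
    orphan <- setdiff(unique(minutes$subject_id), subjects$subject_id)
    if (length(orphan) > 0L) {
      stop("minute records for subject(s) absent from the subjects table: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
    if (nrow(minutes) > 0L) {
      rng <- minutes |>
        dplyr::group_by(.data$subject_id) |>
        dplyr::summarise(first = min(.data$timestamp),
                         last = max(.data$timestamp), .groups = "drop") |>
        dplyr::left_join(subjects, by = "subject_id")
      out_of_window <-
        as.Date(rng$first, tz = "UTC") < rng$study_start |
        as.Date(rng$last, tz = "UTC") > rng$study_end
      if (any(out_of_window)) {
        stop("records outside the study window for subject(s): ",
             paste(utils::head(rng$subject_id[out_of_window], 5),
                   collapse = ", "), call. = FALSE)
      }
    }
  }
  structure(list(minutes = minutes, subjects = subjects), class = "wt_cohort")
}

#' @export
print.wt_cohort <- function(x, ...) {
  n_groups <- length(unique(x$subjects$group))
  cat("<wt_cohort> ", nrow(x$subjects), " subjects in ", n_groups,
      " group(s); ", format(nrow(x$minutes), big.mark = ","),
      " minute records\n", sep = "")
  invisible(x)
}

# Minutes of one subject, with its study window attached as attributes.
subject_minutes <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "wt_cohort"))
  meta <- cohort$subjects[cohort$subjects$subject_id == subject_id, ]
  if (nrow(meta) == 0L) stop("unknown subject: ", subject_id, call. = FALSE)
  m <- cohort$minutes[cohort$minutes$subject_id == subject_id, ]
  attr(m, "study_start") <- meta$study_start
  attr(m, "study_end") <- meta$study_end
  m
}
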