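#' Read minute-level wearable records from CSV
#'
#' Reads the flat minute-record dialect: header
#' `subject_id,group,timestamp,heart_rate,steps`, timestamps in ISO-8601 to
#' minute precision (`YYYY-MM-DDTHH:MM`), empty fields meaning missing, UTF-8
#' with LF line endings. A row with an empty `heart_rate` is a minute in which
#' the device registered no heart rate (not worn); a row with an empty `steps`
#' registered no step count. Minutes with no row at all are simply absent.
#'
#' A `heart_rate` of exactly 0 is treated as sensor dropout and converted to
#' missing, with one warning reporting how many rows were affected.
#'
#' @param path Path to the CSV file.
#' @param study_start,study_end Optional Dates bounding the study window,
#'   applied to every subject in the file. When omitted, each subject's window
#'   is inferred from its first and last record.
#' @return A [wt_cohort()].
#' @export
read_minute_csv <- function(path, study_start = NULL, study_end = NULL) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      group = readr::col_character(),
      timestamp = readr::col_character(),
      heart_rate = readr::col_double(),
      steps = readr::col_integer()
    ),
    progress = FALSE
  )
  expected <- c("subject_id", "group", "timestamp", "heart_rate", "steps")
  if (!identical(names(raw), expected)) {
    stop("unexpected header in ", path, "; expected ",
         paste(expected, collapse = ","), call. = FALSE)
  }

  bad <- !grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}$", raw$timestamp)
  if (any(bad)) {
    # +1 for the header line
    stop("malformed timestamp at line ", which(bad)[1] + 1L, ": '",
         raw$timestamp[which(bad)[1]], "'", call. = FALSE)
  }
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M", tz = "UTC")
  if (anyNA(ts)) {
    stop("unparseable timestamp at line ", which(is.na(ts))[1] + 1L,
         call. = FALSE)
  }

  dup <- duplicated(data.frame(raw$subject_id, ts))
  if (any(dup)) {
    stop("duplicate subject-minute at line ", which(dup)[1] + 1L, " (",
         raw$subject_id[which(dup)[1]], " @ ", raw$timestamp[which(dup)[1]],
         ")", call. = FALSE)
  }

  hr <- raw$heart_rate
  n_zero <- sum(!is.na(hr) & hr == 0)
  if (n_zero > 0L) {
    warning(n_zero, " heart_rate value(s) of 0 treated as missing ",
            "(sensor dropout)", call. = FALSE)
    hr[!is.na(hr) & hr == 0] <- NA_real_
  }

  minutes <- tibble::tibble(
    subject_id = raw$subject_id, group = raw$group, timestamp = ts,
    heart_rate = hr, steps = raw$steps
  )
  subjects <- NULL
  if (!is.null(study_start) || !is.null(study_end)) {
    if (is.null(study_start) || is.null(study_end)) {
      stop("provide both study_start and study_end, or neither",
           call. = FALSE)
    }
    subjects <- minutes |>
      dplyr::distinct(.data$subject_id, .data$group) |>
      dplyr::mutate(study_start = as.Date(study_start),
                    study_end = as.Date(study_end))
  }
  wt_cohort(minutes, subjects)
}

# Format an optional numeric for the CSV dialect: "" when missing, otherwise
# the shortest exact decimal representation.
fmt_opt <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE,
                                 digits = 15)
  }, character(1))
  out
}

#' Write minute-level records to CSV
#'
#' Serialises a cohort's minute records in the dialect read by
#' [read_minute_csv()]: missing heart rate or steps become empty fields and
#' timestamps are written to minute precision. Rows are ordered by subject
#' then timestamp, so the output is byte-identical for identical cohorts.
#'
#' @param cohort A [wt_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_minute_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "wt_cohort"))
  m <- dplyr::arrange(cohort$minutes, .data$subject_id, .data$timestamp)
  lines <- c(
    "subject_id,group,timestamp,heart_rate,steps",
    sprintf("%s,%s,%s,%s,%s",
            m$subject_id, m$group,
            format(m$timestamp, "%Y-%m-%dT%H:%M", tz = "UTC"),
            fmt_opt(m$heart_rate), fmt_opt(m$steps))
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write day summaries to CSV
#'
#' One row per subject-day with all validity flags. The dialect fixes
#' `wear_fraction` at six decimals; `mean_hr` is written at full precision and
#' left empty for days with zero wear. Validity flags are `true`/`false`.
#'
#' @param summaries Day-summary tibble from [summarize_days()]; must be
#'   non-empty.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_day_summaries()] for the lossless inverse.
#' @export
write_day_summaries <- function(summaries, path) {
  if (nrow(summaries) == 0L) {
    stop("refusing to write an empty day-summary table", call. = FALSE)
  }
  valid_cols <- grep("^valid_", names(summaries), value = TRUE)
  header <- paste(c("subject_id", "date", "wear_minutes", "wear_fraction",
                    "total_steps", "mean_hr", valid_cols), collapse = ",")
  flag_part <- if (length(valid_cols) > 0L) {
    do.call(paste, c(lapply(valid_cols, function(cl) {
      ifelse(summaries[[cl]], "true", "false")
    }), sep = ","))
  } else {
    character(nrow(summaries))
  }
  body <- sprintf("%s,%s,%d,%.6f,%d,%s%s",
                  summaries$subject_id,
                  format(summaries$date, "%Y-%m-%d"),
                  as.integer(summaries$wear_minutes),
                  summaries$wear_fraction,
                  as.integer(summaries$total_steps),
                  fmt_opt(summaries$mean_hr),
                  if (length(valid_cols) > 0L) paste0(",", flag_part) else "")
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read day summaries from CSV
#'
#' Inverse of [write_day_summaries()]. `wear_fraction` is recomputed as
#' `wear_minutes / 1440` so the exact invariant survives the fixed six-decimal
#' serialisation.
#'
#' @param path Path to a day-summary CSV.
#' @return A day-summary tibble.
#' @export
read_day_summaries <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    date = readr::col_date(),
    wear_minutes = readr::col_integer(),
    wear_fraction = readr::col_double(),
    total_steps = readr::col_integer(),
    mean_hr = readr::col_double(),
    .default = readr::col_logical()
  ), progress = FALSE)
  recomputed <- raw$wear_minutes / 1440
  if (any(abs(recomputed - raw$wear_fraction) > 5e-7)) {
    stop("wear_fraction inconsistent with wear_minutes / 1440 in ", path,
         call. = FALSE)
  }
  raw$wear_fraction <- recomputed
  raw
}
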