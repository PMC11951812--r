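#' Define a valid-day rule
#'
#' A valid-day rule is a named predicate over daily summaries. A day passes
#' the rule when its registered step total strictly exceeds `min_steps` (if
#' set) and its wear fraction strictly exceeds `min_wear_fraction` (if set).
#' Both thresholds are strict ("greater than"), so a day with exactly 1000
#' steps fails a 1000-step floor and a day worn exactly 80% of its 1440
#' minutes fails a 0.8 wear-fraction floor.
#'
#' @param name Rule name; used as the `valid_<name>` column suffix in day
#'   summaries, so it should be a lowercase identifier.
#' @param min_steps Step floor (steps/day), or `NULL` for no step criterion.
#' @param min_wear_fraction Wear-fraction floor in `[0, 1]`, or `NULL` for no
#'   wear criterion. A floor of 0.8 corresponds to 19.2 hours of a 24-hour day.
#'
#' @return An object of class `wt_rule`: a list with fields `name`,
#'   `min_steps`, `min_wear_fraction`.
#' @seealso [default_rules()] for the three standard presets,
#'   [classify_valid_day()] to apply a rule.
#' @export
#' @examples
#' valid_day_rule("weartime80", min_wear_fraction = 0.8)
#' valid_day_rule("custom", min_steps = 500, min_wear_fraction = 0.5)
valid_day_rule <- function(name, min_steps = NULL, min_wear_fraction = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (grepl("[^a-z0-9_]", name)) {
    stop("rule name must be a lowercase identifier (a-z, 0-9, _): ", name,
         call. = FALSE)
  }
  if (!is.null(min_steps)) {
    stopifnot(is.numeric(min_steps), length(min_steps) == 1L, min_steps >= 0)
  }
  if (!is.null(min_wear_fraction)) {
    stopifnot(is.numeric(min_wear_fraction), length(min_wear_fraction) == 1L,
              min_wear_fraction >= 0, min_wear_fraction <= 1)
  }
  structure(
    list(name = name, min_steps = min_steps,
         min_wear_fraction = min_wear_fraction),
    class = "wt_rule"
  )
}

#' @export
print.wt_rule <- function(x, ...) {
  crit <- c(
    if (!is.null(x$min_steps)) paste0("steps > ", x$min_steps),
    if (!is.null(x$min_wear_fraction))
      paste0("wear fraction > ", x$min_wear_fraction)
  )
  if (length(crit) == 0L) crit <- "all days valid"
  cat("<valid-day rule> ", x$name, ": ", paste(crit, collapse = " and "),
      "\n", sep = "")
  invisible(x)
}

#' Standard valid-day rule presets
#'
#' The three definitions commonly compared in wear-time sensitivity analyses:
#'
#' * `none` — every day is valid, including days with zero records (a device
#'   that was received but never worn still contributes 0-step days);
#' * `stepcount1000` — a day is valid if its registered step count is greater
#'   than 1000;
#' * `weartime80` — a day is valid if its wear time over the 24-hour day is
#'   greater than 80% (19.2 hours).
#'
#' @param names Subset of preset names to return. Defaults to all three.
#' @return A named list of [valid_day_rule()] objects.
#' @export
#' @examples
#' default_rules()
#' default_rules(c("none", "weartime80"))
default_rules <- function(names = c("none", "stepcount1000", "weartime80")) {
  presets <- list(
    none          = valid_day_rule("none"),
    stepcount1000 = valid_day_rule("stepcount1000", min_steps = 1000),
    weartime80    = valid_day_rule("weartime80", min_wear_fraction = 0.8)
  )
  unknown <- setdiff(names, names(presets))
  if (length(unknown) > 0L) {
    stop("unknown rule preset(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  presets[names]
}

# Normalise a rules argument: a single rule or a list of rules -> named list.
as_rule_list <- function(rules) {
  if (inherits(rules, "wt_rule")) rules <- list(rules)
  if (!is.list(rules) || length(rules) == 0L ||
      !all(vapply(rules, inherits, logical(1), "wt_rule"))) {
    stop("`rules` must be a wt_rule or a non-empty list of wt_rule objects",
         call. = FALSE)
  }
  stats::setNames(rules, vapply(rules, `[[`, character(1), "name"))
}

#' Classify days as valid under a rule
#'
#' Applies a valid-day rule to a day-summary table. The predicate uses strict
#' inequalities: a day is valid iff `total_steps > min_steps` (when a step
#' floor is set) and `wear_fraction > min_wear_fraction` (when a wear floor is
#' set). A rule with neither threshold accepts every day.
#'
#' @param summaries Day-summary tibble from [summarize_days()] (only the
#'   `total_steps` and `wear_fraction` columns are consulted).
#' @param rule A [valid_day_rule()].
#' @return Logical vector with one element per row of `summaries`.
#' @export
#' @examples
#' s <- tibble::tibble(total_steps = c(900, 1000, 1001),
#'                     wear_fraction = c(1, 1, 1))
#' classify_valid_day(s, default_rules()$stepcount1000)
classify_valid_day <- function(summaries, rule) {
  stopifnot(inherits(rule, "wt_rule"),
            all(c("total_steps", "wear_fraction") %in% names(summaries)))
  ok <- rep(TRUE, nrow(summaries))
  if (!is.null(rule$min_steps)) {
    ok <- ok & summaries$total_steps > rule$min_steps
  }
  if (!is.null(rule$min_wear_fraction)) {
    ok <- ok & summaries$wear_fraction > rule$min_wear_fraction
  }
  ok
}
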