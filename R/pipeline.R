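#' Run the wear-time analysis pipeline end to end
#'
#' Single entry point tying the modules together: obtain a cohort (read a
#' minute CSV or simulate one), summarise days under the valid-day rules,
#' run the rule-sensitivity analysis, the walking-heart-rate analysis, the
#' monthly wear trend, and the group compliance comparison, writing each
#' product as CSV into `out_dir` together with a flat key-value run manifest
#' (parameters, seed, and md5 checksum of every output), so a run can be
#' reproduced byte-for-byte from its manifest.
#'
#' @param out_dir Output directory (created if needed).
#' @param input Path to a minute-record CSV, or `NULL` to simulate.
#' @param configs List of [synthetic_group_config()] for simulation, or
#'   `NULL` to read `input`. Exactly one of `input`/`configs` must be given.
#' @param rules Valid-day rules (list of [valid_day_rule()]).
#' @param steps Which stages to run; `"all"` (default) runs everything.
#' @param cadence_threshold,se_threshold,repetitions,grid_cap Walking-HR
#'   parameters, see [walking_hr_analysis()].
#' @param seed Integer seed; required when simulating or running the
#'   (stochastic) walking-HR stage.
#' @param study_start,study_end Optional study window for `input` mode,
#'   passed to [read_minute_csv()].
#' @param alpha Significance level of the group comparison.
#' @param quiet Suppress progress messages?
#' @return Invisibly, a list of the in-memory products (`cohort`,
#'   `summaries`, `estimates`, and the stage outputs that ran).
#' @export
run_pipeline <- function(out_dir, input = NULL, configs = NULL,
                         rules = default_rules(),
                         steps = c("all", "summarize", "sensitivity",
                                   "walking_hr", "compare"),
                         cadence_threshold = 80, se_threshold = 1,
                         repetitions = 100, grid_cap = 1000, seed = NULL,
                         study_start = NULL, study_end = NULL,
                         alpha = 0.05, quiet = FALSE) {
  steps <- match.arg(steps, several.ok = TRUE)
  if ("all" %in% steps) steps <- c("summarize", "sensitivity", "walking_hr",
                                   "compare")
  if (is.null(input) == is.null(configs)) {
    stop("provide exactly one of `input` (minute CSV) or `configs` ",
         "(simulation)", call. = FALSE)
  }
  if (!is.null(configs) && is.null(seed)) {
    stop("`seed` is required when simulating", call. = FALSE)
  }
  if ("walking_hr" %in% steps && is.null(seed)) {
    stop("`seed` is required for the walking-heart-rate stage", call. = FALSE)
  }
  rules <- as_rule_list(rules)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path, progress = FALSE)
    outputs <<- c(outputs, name)
    path
  }

  products <- list()
  if (!is.null(configs)) {
    say("simulating cohort (seed ", seed, ") ...")
    sim <- generate_cohort(configs, master_seed = seed, dir = out_dir)
    outputs <- c(outputs, "minutes.csv", "truth.csv")
    cohort <- sim$cohort
    products$truth <- sim$truth
  } else {
    if (!file.exists(input)) stop("input file not found: ", input,
                                  call. = FALSE)
    say("reading ", input, " ...")
    cohort <- read_minute_csv(input, study_start, study_end)
  }
  products$cohort <- cohort

  say("summarising days ...")
  summaries <- summarize_days(cohort, rules)
  products$summaries <- summaries
  emit(summaries, "day_summaries.csv")
  write_day_summaries(summaries, file.path(out_dir, "day_summaries_dialect.csv"))
  outputs <- c(outputs, "day_summaries_dialect.csv")
  estimates <- estimate_subjects(summaries, rules)
  products$estimates <- estimates
  emit(estimates, "subject_estimates.csv")
  trend <- monthly_wear_trend(summaries, cohort$subjects)
  products$monthly_trend <- trend
  emit(trend, "monthly_wear_trend.csv")

  if ("sensitivity" %in% steps) {
    say("rule-sensitivity analysis ...")
    pop <- population_estimates(summaries, rules)
    products$population <- pop
    emit(pop, "population_estimates.csv")
    if (length(rules) >= 2L) {
      rule_a <- rules[[1]]; rule_b <- rules[[length(rules)]]
      diffs <- individual_differences(summaries, rule_a, rule_b)
      products$differences <- diffs
      emit(diffs, "individual_differences.csv")
      emit(bin_differences(diffs), "difference_bins.csv")
      emit(misclassification_report(summaries, rule_a, rule_b),
           "misclassification.csv")
    }
  }

  if ("walking_hr" %in% steps) {
    say("walking-heart-rate analysis ...")
    ref <- if ("weartime80" %in% names(rules)) rules$weartime80 else
      rules[[length(rules)]]
    wh <- walking_hr_analysis(cohort, summaries, reference_rule = ref,
                              cadence_threshold = cadence_threshold,
                              se_threshold = se_threshold,
                              repetitions = repetitions,
                              grid_cap = grid_cap, seed = seed)
    products$walking <- wh
    emit(wh, "walking_hr.csv")
  }

  if ("compare" %in% steps) {
    say("group compliance comparison ...")
    cmp <- wear_group_comparison(summaries, alpha = alpha)
    products$comparison <- cmp
    emit(cmp$omnibus, "wear_omnibus.csv")
    if (!is.null(cmp$pairwise)) emit(cmp$pairwise, "wear_pairwise.csv")
  }

  manifest <- c(
    paste0("package_version=", as.character(utils::packageVersion("weartime"))),
    paste0("mode=", if (is.null(input)) "simulate" else "input"),
    if (!is.null(input)) paste0("input=", normalizePath(input)),
    if (!is.null(input)) paste0("input_md5=", unname(tools::md5sum(input))),
    paste0("rules=", paste(names(rules), collapse = ",")),
    paste0("cadence_threshold=", cadence_threshold),
    paste0("se_threshold=", se_threshold),
    paste0("repetitions=", repetitions),
    paste0("grid_cap=", grid_cap),
    paste0("seed=", if (is.null(seed)) "" else seed),
    paste0("steps=", paste(steps, collapse = ",")),
    vapply(sort(outputs), function(f) {
      paste0("output_md5_", f, "=",
             unname(tools::md5sum(file.path(out_dir, f))))
    }, character(1))
  )
  readr::write_lines(manifest, file.path(out_dir, "manifest.txt"))
  say("wrote ", length(outputs), " output file(s) and manifest to ", out_dir)
  invisible(products)
}
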