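#' Kruskal-Wallis omnibus test on per-subject compliance
#'
#' Rank-based omnibus test for a difference in location between groups, the
#' appropriate choice when group variances and sample sizes differ markedly.
#' This is a thin wrapper around [stats::kruskal.test()] returning a tidy
#' one-row summary (H statistic with tie correction, degrees of freedom,
#' p-value from the chi-squared approximation).
#'
#' @param values Numeric vector, one value per subject (typically the
#'   subject's study-average daily wear fraction).
#' @param groups Group label for each value.
#' @return One-row tibble: `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, n = length(values))
}

#' Dunn pairwise post hoc comparisons
#'
#' Follow-up to a significant Kruskal-Wallis omnibus: for every pair of
#' groups, the standardised difference of mean ranks
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}}
#' with ranks over the pooled data and the usual tie correction. Two-sided
#' p-values come from the standard normal; Holm-adjusted p-values are
#' reported alongside the raw ones.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level for the `significant` flag.
#' @param adjust P-value adjustment method for the flags (any
#'   [stats::p.adjust()] method; `"none"` flags on raw p-values).
#' @return Tibble with one row per unordered pair: `group_i`, `group_j`,
#'   `z` (sign: mean rank of `group_i` minus `group_j`), `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05, adjust = "holm") {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 subjects", call. = FALSE)
  }

  r <- rank(values)
  n_tot <- length(values)
  mean_rank <- tapply(r, groups, mean)
  n_g <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties)
  var_base <- n_tot * (n_tot + 1) / 12 - tie_term / (12 * (n_tot - 1))

  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_base * (1 / n_g[[i]] + 1 / n_g[[j]]))
    z[k] <- if (se == 0) 0 else (mean_rank[[i]] - mean_rank[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  p_adj <- stats::p.adjust(p, method = adjust)
  tibble::tibble(
    group_i = pairs[1, ], group_j = pairs[2, ],
    z = z, p_raw = p, p_adjusted = p_adj,
    significant = p_adj < alpha
  )
}

#' Group comparison of wear-time compliance
#'
#' Convenience wrapper reproducing the standard compliance analysis: each
#' subject is summarised by its study-average daily wear fraction, the
#' Kruskal-Wallis omnibus is run across groups, and — when the omnibus is
#' significant at `alpha` — Dunn pairwise comparisons follow. Groups with
#' fewer than two subjects cannot enter a rank test and are excluded with a
#' warning (they remain in `per_subject`).
#'
#' @param summaries Day-summary tibble from [summarize_days()] (empty days
#'   included, so never-worn subjects enter at 0).
#' @param alpha Significance level.
#' @param adjust Adjustment method for the pairwise p-value flags.
#' @return List with elements `per_subject` (subject-level wear), `omnibus`
#'   (from [kruskal_wallis()]), and `pairwise` (from [dunn_posthoc()];
#'   `NULL` when the omnibus is not significant).
#' @export
wear_group_comparison <- function(summaries, alpha = 0.05, adjust = "holm") {
  per_subject <- summaries |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(mean_wear_fraction = mean(.data$wear_fraction),
                     .groups = "drop")
  sizes <- table(per_subject$group)
  small <- names(sizes)[sizes < 2]
  tested <- per_subject
  if (length(small) > 0L) {
    warning("group(s) with fewer than 2 subjects excluded from the ",
            "comparison: ", paste(small, collapse = ", "), call. = FALSE)
    tested <- per_subject[!per_subject$group %in% small, ]
  }
  omnibus <- kruskal_wallis(tested$mean_wear_fraction, tested$group)
  pairwise <- NULL
  if (omnibus$p_value < alpha) {
    pairwise <- dunn_posthoc(tested$mean_wear_fraction, tested$group,
                             alpha = alpha, adjust = adjust)
  }
  list(per_subject = per_subject, omnibus = omnibus, pairwise = pairwise)
}
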