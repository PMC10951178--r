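#' One-sample t-test with effect size
#'
#' Cohort-level test used on the solved deterministic proportions (is the
#' mean `d` different from 0?). Wraps [stats::t.test()] and adds Cohen's d
#' computed as `(mean - mu0) / SD`.
#'
#' @param values Numeric vector, length >= 2, non-zero SD.
#' @param mu0 Null value (default 0).
#' @return One-row tibble: `kind`, `estimate` (mean), `statistic` (t), `df`,
#'   `p_value`, `cohens_d`, `n`.
#' @examples
#' one_sample_t(c(1, 2, 3, 4, 5))
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) {
    abort("Need at least 2 non-missing values for a t-test.")
  }
  s <- sd(values)
  if (s == 0) {
    abort("Zero standard deviation: t statistic undefined.")
  }
  ht <- stats::t.test(values, mu = mu0)
  tibble(
    kind = "one_sample_t",
    estimate = mean(values),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    cohens_d = (mean(values) - mu0) / s,
    n = n
  )
}

#' Paired t-test with effect size
#'
#' Used for the within-participant comparisons (`s1` vs `s2`, `d1` vs `d2`,
#' cued vs uncued `P2 - P1`). Equivalent to a one-sample t-test on the
#' differences `x - y`; Cohen's d uses the SD of the differences.
#'
#' @param x,y Equal-length numeric vectors (pairs with a missing member are
#'   dropped).
#' @return One-row tibble as in [one_sample_t()] with `kind = "paired_t"`
#'   and `estimate` the mean difference. Exactly identical vectors (every
#'   difference zero) return `statistic = 0`, `p_value = 1`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length for a paired test.")
  }
  ok <- !is.na(x) & !is.na(y)
  diffs <- x[ok] - y[ok]
  if (length(diffs) >= 2 && all(diffs == 0)) {
    return(tibble(kind = "paired_t", estimate = 0, statistic = 0,
                  df = length(diffs) - 1, p_value = 1, cohens_d = 0,
                  n = length(diffs)))
  }
  out <- one_sample_t(diffs)
  out$kind <- "paired_t"
  out
}

#' Miss-rate difference (P2 - P1) by cue condition
#'
#' The primary cueing outcome: per participant, the change in miss rate from
#' first to second appearance, separately for the `noCue-noCue` and
#' `noCue-Cue` display groups, and the paired test of whether the cue made
#' the drop larger. Participants missing either condition are dropped with a
#' warning.
#'
#' @param estimates Estimates tibble from [decompose_cohort()] (or any table
#'   with `participant_id`, `condition`, `P1`, `P2`).
#' @return A `miss_rate_diff` object; [tidy()] returns the per-participant
#'   differences, [glance()] the paired test.
#' @export
miss_rate_diff <- function(estimates) {
  stopifnot(all(c("participant_id", "condition", "P1", "P2") %in%
                  names(estimates)))
  diffs <- estimates |>
    dplyr::mutate(p2_minus_p1 = .data$P2 - .data$P1) |>
    dplyr::select(dplyr::all_of(c("participant_id", "condition",
                                  "p2_minus_p1")))
  wide <- diffs |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = "p2_minus_p1")
  conds <- setdiff(names(wide), "participant_id")
  if (length(conds) != 2) {
    abort("miss_rate_diff() needs exactly two conditions.")
  }
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warn(sprintf("%d participant(s) missing a condition were dropped.",
                 sum(!complete)))
    wide <- wide[complete, ]
  }
  test <- paired_t(wide[[conds[1]]], wide[[conds[2]]])
  test$comparison <- paste(conds[1], "vs", conds[2])
  structure(list(differences = diffs, test = test), class = "miss_rate_diff")
}

#' @export
print.miss_rate_diff <- function(x, ...) {
  cat(sprintf("<miss_rate_diff: %s; t(%d) = %.3f, p = %.4g>\n",
              x$test$comparison, x$test$df, x$test$statistic,
              x$test$p_value))
  invisible(x)
}

#' @method tidy miss_rate_diff
#' @export
tidy.miss_rate_diff <- function(x, ...) x$differences

#' @method glance miss_rate_diff
#' @export
glance.miss_rate_diff <- function(x, ...) x$test

#' Hit rate as a function of target-background contrast
#'
#' Bins target-present trials by signed T-B contrast (default bin width 50
#' for continuous contrasts; discrete designs with few levels are summarized
#' level-wise), computes each participant's hit rate per bin, and averages
#' across participants with an SEM (SD across participants / sqrt(n)).
#'
#' @param trials Trial tibble with `tb_contrast`.
#' @param bin_width Bin width on the signed contrast axis.
#' @param discrete Treat each distinct contrast value as its own level;
#'   defaults to `TRUE` when there are at most 12 distinct values.
#' @return Tibble of class `binned_hit_rates`: `tb_center`, `hit_rate`,
#'   `sem`, `n_participants`.
#' @export
bin_hit_rates <- function(trials, bin_width = 50, discrete = NULL) {
  present <- trials |>
    dplyr::filter(.data$target_present, !is.na(.data$tb_contrast))
  if (nrow(present) == 0) {
    abort("No target-present trials with contrast values.")
  }
  if (is.null(discrete)) {
    discrete <- dplyr::n_distinct(present$tb_contrast) <= 12
  }
  present$tb_center <- if (discrete) {
    present$tb_contrast
  } else {
    (floor(present$tb_contrast / bin_width) + 0.5) * bin_width
  }
  out <- present |>
    dplyr::group_by(.data$participant_id, .data$tb_center) |>
    dplyr::summarise(hit = mean(.data$response == "present"),
                     .groups = "drop") |>
    dplyr::group_by(.data$tb_center) |>
    dplyr::summarise(
      hit_rate = mean(.data$hit),
      sem = sd(.data$hit) / sqrt(dplyr::n()),
      n_participants = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$tb_center)
  class(out) <- c("binned_hit_rates", class(out))
  out
}

#' Observed P12 against its stochastic and deterministic predictions
#'
#' The paradigm's signature figure as a table: per participant (and
#' condition), the observed `(P1, P12)` point together with the stochastic
#' prediction `P1 * P2` and the deterministic prediction `min(P1, P2)`.
#' Where observed P12 falls between the two shows the error mixture at a
#' glance. Plot with [ggplot2::autoplot()].
#'
#' @param estimates Estimates tibble with `P1`, `P2`, `P12` (predictions are
#'   recomputed if absent).
#' @return Tibble of class `p12_table`.
#' @export
scatter_p12 <- function(estimates) {
  stopifnot(all(c("P1", "P2", "P12") %in% names(estimates)))
  if (!all(c("stoch_pred", "det_pred") %in% names(estimates))) {
    estimates <- predictions(estimates)
  }
  keep <- intersect(c("participant_id", "condition", "P1", "P2", "P12",
                      "stoch_pred", "det_pred"), names(estimates))
  out <- estimates |> dplyr::select(dplyr::all_of(keep))
  class(out) <- c("p12_table", class(out))
  out
}

#' Descriptive reaction-time summary per design cell
#'
#' Mean correct-trial RT and across-participant SEM per cell of target
#' presence x set size x repetition (x cue condition when present). Purely
#' descriptive; no inferential RT statistics are produced.
#'
#' @param trials Trial tibble.
#' @param correct_only Summarise correct responses only (default `TRUE`).
#' @return Tibble with cell columns, `mean_rt_ms`, `sem`, `n_participants`.
#' @export
rt_summary <- function(trials, correct_only = TRUE) {
  cells <- intersect(c("target_present", "set_size", "copy",
                       "cue_condition"), names(trials))
  if (correct_only) {
    trials <- trials |>
      dplyr::filter(.data$response ==
                      ifelse(.data$target_present, "present", "absent"))
  }
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant_id",
                                                  cells)))) |>
    dplyr::summarise(rt = mean(.data$rt_ms), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cells))) |>
    dplyr::summarise(
      mean_rt_ms = mean(.data$rt),
      sem = sd(.data$rt) / sqrt(dplyr::n()),
      n_participants = dplyr::n(),
      .groups = "drop"
    )
}
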