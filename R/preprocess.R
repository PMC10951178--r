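#' Flag reaction-time outliers per design cell
#'
#' Applies the two-stage RT screen: trials with extreme RTs (longer than
#' `extreme_cutoff_ms`, default 100 s) are flagged first so they cannot
#' distort the cell statistics; then, per participant and per cell of
#' `cells`, trials whose RT is strictly outside mean +/- `k_sd` standard
#' deviations (computed without the extreme trials) are flagged. Equality at
#' the boundary is retained, and a degenerate cell (SD 0 or a single trial)
#' flags nothing. The function only flags — pairing-aware removal is
#' [pair_removal()]'s job.
#'
#' @param trials Trial tibble (simulated or read from a trial log).
#' @param cells Character vector of column names defining a trimming cell,
#'   in addition to `participant_id`. Use
#'   `c("target_present", "set_size")` for the uncued dialects and
#'   `c("target_present", "set_size", "copy", "cue_condition")` for the cued
#'   dialect, where trimming is per condition.
#' @param k_sd Trim multiplier (default 2.5).
#' @param extreme_cutoff_ms Extreme-RT screen (default 1e5 ms = 100 s).
#' @return The input tibble with logical columns `excluded_extreme` and
#'   `excluded_rt_outlier` added.
#' @export
trim_rts <- function(trials, cells = c("target_present", "set_size"),
                     k_sd = 2.5, extreme_cutoff_ms = 1e5) {
  stopifnot(all(c("participant_id", "rt_ms", cells) %in% names(trials)),
            all(trials$rt_ms > 0))
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant_id", cells)))) |>
    dplyr::mutate(
      excluded_extreme = .data$rt_ms > .env$extreme_cutoff_ms,
      excluded_rt_outlier = rt_outlier_flag(.data$rt_ms,
                                            .data$excluded_extreme,
                                            .env$k_sd)
    ) |>
    dplyr::ungroup()
}

rt_outlier_flag <- function(rt, extreme, k_sd) {
  ok <- !extreme
  if (sum(ok) < 2) {
    return(rep(FALSE, length(rt)))
  }
  m <- mean(rt[ok])
  s <- sd(rt[ok])
  if (!is.finite(s) || s == 0) {
    return(rep(FALSE, length(rt)))
  }
  ok & (rt < m - k_sd * s | rt > m + k_sd * s)
}

#' Remove flagged trials together with their paired copies
#'
#' Drops every trial flagged for removal and, because the double-pass
#' analysis needs complete display pairs, also drops the surviving copy of
#' any display that lost a trial. Input must contain complete pairs (every
#' `display_id` twice per participant); an orphan id is a validation error.
#'
#' @param trials Trial tibble, typically after [trim_rts()].
#' @param remove_cols Logical columns marking trials for removal. Columns
#'   absent from the input are ignored, so the default covers both the
#'   RT flags and the motor-correction flag.
#' @return The surviving trials (complete pairs only), flag columns dropped.
#' @export
pair_removal <- function(trials,
                         remove_cols = c("excluded_extreme",
                                         "excluded_rt_outlier", "corrected")) {
  counts <- trials |>
    dplyr::count(.data$participant_id, .data$display_id)
  if (any(counts$n != 2L)) {
    bad <- counts |> dplyr::filter(.data$n != 2L)
    abort(sprintf(
      "Input must contain complete display pairs; %d display(s) appear %s times (e.g. %s / %s).",
      nrow(bad), paste(unique(bad$n), collapse = "/"),
      bad$participant_id[1], bad$display_id[1]))
  }
  remove_cols <- intersect(remove_cols, names(trials))
  flagged <- rep(FALSE, nrow(trials))
  for (col in remove_cols) {
    flagged <- flagged | trials[[col]]
  }
  lost <- unique(trials[flagged, c("participant_id", "display_id")])
  out <- dplyr::anti_join(trials, lost,
                          by = c("participant_id", "display_id"))
  out[setdiff(names(out), c("excluded_extreme", "excluded_rt_outlier"))]
}

#' Detection sensitivity (d') per participant
#'
#' Computes hit rate over target-present trials, false-alarm rate over
#' target-absent trials, and d' = z(HR) - z(FAR). Boundary rates are
#' corrected before the z-transform: a rate of 1 becomes `(n - 0.5)/n` and a
#' rate of 0 becomes `0.5/n` (the standard half-count correction), keeping d'
#' finite.
#'
#' @param trials Trial tibble with `participant_id`, `target_present`,
#'   `response`.
#' @return Tibble with one row per participant: `n_present`, `n_absent`,
#'   `hit_rate`, `fa_rate` (corrected values), `dprime`.
#' @export
dprime <- function(trials) {
  stats_tbl <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_present = sum(.data$target_present),
      n_absent = sum(!.data$target_present),
      hits = sum(.data$target_present & .data$response == "present"),
      fas = sum(!.data$target_present & .data$response == "present"),
      .groups = "drop"
    )
  if (any(stats_tbl$n_present == 0) || any(stats_tbl$n_absent == 0)) {
    abort("d' needs at least one target-present and one target-absent trial per participant.")
  }
  stats_tbl |>
    dplyr::mutate(
      hit_rate = correct_rate(.data$hits, .data$n_present),
      fa_rate = correct_rate(.data$fas, .data$n_absent),
      dprime = qnorm(.data$hit_rate) - qnorm(.data$fa_rate)
    ) |>
    dplyr::select(!dplyr::all_of(c("hits", "fas")))
}

correct_rate <- function(k, n) {
  r <- k / n
  dplyr::case_when(r == 0 ~ 0.5 / n, r == 1 ~ (n - 0.5) / n, TRUE ~ r)
}

#' Screen participants by group-relative d'
#'
#' Excludes participants whose d' lies strictly outside the group mean +/-
#' `k_sd` group standard deviations (each experiment screened against its own
#' cohort). With fewer than three participants there is no meaningful group
#' distribution, so screening is skipped with a warning.
#'
#' @param trials Trial tibble (post-exclusion) covering the whole cohort.
#' @param k_sd Screening multiplier (default 2.5).
#' @return Tibble per participant: `dprime`, `excluded`, `reason`
#'   (`"low_dprime"` / `"high_dprime"` or `NA`).
#' @export
screen_participants <- function(trials, k_sd = 2.5) {
  dp <- dprime(trials)
  if (nrow(dp) < 3) {
    warn("Fewer than 3 participants: d' screening skipped.")
    return(dp |> dplyr::mutate(excluded = FALSE, reason = NA_character_))
  }
  m <- mean(dp$dprime)
  s <- sd(dp$dprime)
  dp |>
    dplyr::mutate(
      excluded = s > 0 & abs(.data$dprime - m) > k_sd * s,
      reason = dplyr::case_when(
        .data$excluded & .data$dprime < m ~ "low_dprime",
        .data$excluded ~ "high_dprime",
        TRUE ~ NA_character_
      )
    )
}

#' Run the full exclusion pipeline on a cohort trial log
#'
#' Chains the published exclusion order — extreme-RT screen, per-cell 2.5-SD
#' trim, motor-correction removal, paired-copy removal, then d'-based
#' participant screening — and returns both the surviving trials and a
#' bookkeeping report.
#'
#' @param trials Cohort trial tibble.
#' @param cells Trimming cells passed to [trim_rts()].
#' @param k_sd Trim and screening multiplier.
#' @param extreme_cutoff_ms Extreme-RT cutoff in ms.
#' @return A list of class `preprocess_result`:
#'   * `trials` — surviving trials of retained participants;
#'   * `summary` — one-row tibble: `n_trials`, `n_extreme_rt_removed`,
#'     `pct_outlier_rt`, `pct_corrected`, `pct_removed_by_pairing`,
#'     `pct_remaining_after_pairing` (percentages of the original trial
#'     count; the four removal/remaining percentages sum to 100);
#'   * `participants` — the [screen_participants()] table.
#' @export
preprocess_cohort <- function(trials, cells = c("target_present", "set_size"),
                              k_sd = 2.5, extreme_cutoff_ms = 1e5) {
  n_total <- nrow(trials)
  flagged <- trim_rts(trials, cells = cells, k_sd = k_sd,
                      extreme_cutoff_ms = extreme_cutoff_ms)
  has_corr <- "corrected" %in% names(flagged)
  n_extreme <- sum(flagged$excluded_extreme)
  n_outlier <- sum(flagged$excluded_rt_outlier & !flagged$excluded_extreme)
  direct <- flagged$excluded_extreme | flagged$excluded_rt_outlier
  n_corrected <- if (has_corr) sum(flagged$corrected & !direct) else 0L

  clean <- pair_removal(flagged)
  n_remaining <- nrow(clean)
  n_pairing <- n_total - n_remaining - n_extreme - n_outlier - n_corrected

  screening <- screen_participants(clean, k_sd = k_sd)
  keep <- screening$participant_id[!screening$excluded]
  kept <- clean |> dplyr::filter(.data$participant_id %in% keep)

  summary <- tibble(
    n_trials = n_total,
    n_extreme_rt_removed = n_extreme,
    pct_outlier_rt = 100 * (n_extreme + n_outlier) / n_total,
    pct_corrected = 100 * n_corrected / n_total,
    pct_removed_by_pairing = 100 * n_pairing / n_total,
    pct_remaining_after_pairing = 100 * n_remaining / n_total
  )
  structure(list(trials = kept, summary = summary,
                 participants = screening),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<preprocess_result: %d trials in; %.2f%% RT outliers, ",
           "%.2f%% corrected, %.2f%% remained; %d/%d participants kept>\n"),
    s$n_trials, s$pct_outlier_rt, s$pct_corrected,
    s$pct_remaining_after_pairing,
    sum(!x$participants$excluded), nrow(x$participants)))
  invisible(x)
}
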