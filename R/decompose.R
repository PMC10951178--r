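#' Observed double-pass miss rates (P1, P2, P12)
#'
#' For each participant (and optional condition grouping), restricts to
#' target-present displays whose two copies both survived preprocessing and
#' computes: `P1`, the proportion missed on the first appearance; `P2`, on
#' the second; and `P12`, the proportion of display pairs missed on both.
#' These three observables carry all the information the decomposition
#' needs: stochastic errors predict `P12 = P1 * P2`, deterministic errors
#' predict `P12 = min(P1, P2)`.
#'
#' @param trials Paired trial tibble (after [pair_removal()]).
#' @param condition Optional character vector of trial columns (constant
#'   within a display pair, e.g. `"cue_group"`) to stratify by.
#' @return Tibble with `participant_id`, any condition columns, `P1`, `P2`,
#'   `P12`, `n_pairs`.
#' @export
compute_rates <- function(trials, condition = NULL) {
  present <- trials |> dplyr::filter(.data$target_present)
  if (nrow(present) == 0) {
    abort("No surviving target-present pairs.")
  }
  pairs <- present |>
    dplyr::mutate(miss = .data$response == "absent") |>
    dplyr::select(dplyr::all_of(c("participant_id", "display_id", "copy",
                                  "miss", condition))) |>
    tidyr::pivot_wider(names_from = "copy", values_from = "miss",
                       names_prefix = "miss_")
  if (!all(c("miss_1", "miss_2") %in% names(pairs)) ||
      anyNA(pairs$miss_1) || anyNA(pairs$miss_2)) {
    abort("Trials must form complete pairs (both copies present); run pair_removal() first.")
  }
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("participant_id",
                                                  condition)))) |>
    dplyr::summarise(
      P1 = mean(.data$miss_1),
      P2 = mean(.data$miss_2),
      P12 = mean(.data$miss_1 & .data$miss_2),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
}

#' Compose expected (P1, P2, P12) from latent parameters
#'
#' The forward model: given round-1/round-2 deterministic proportions and
#' stochastic rates, returns the expected observed miss rates
#' \deqn{P1 = d1(1-s1) + s1}
#' \deqn{P2 = d2 + s2(d1-d2) + (1-d1)s2}
#' \deqn{P12 = d2 + s2(d1-d2) + s1(1-d1)s2.}
#' With `d1 = d2 = d` these reduce to `P1 = d + s1(1-d)`,
#' `P2 = d + s2(1-d)`, `P12 = d + s1 s2 (1-d)`. Vectorized over all
#' arguments.
#'
#' @param d1,d2 Deterministic proportions (d2 defaults to d1).
#' @param s1,s2 Stochastic miss rates.
#' @return Tibble with columns `P1`, `P2`, `P12`.
#' @examples
#' compose_rates(d1 = 0.05, s1 = 0.12, s2 = 0.08)
#' @export
compose_rates <- function(d1, s1, s2, d2 = d1) {
  tibble(
    P1 = d1 * (1 - s1) + s1,
    P2 = d2 + s2 * (d1 - d2) + (1 - d1) * s2,
    P12 = d2 + s2 * (d1 - d2) + s1 * (1 - d1) * s2
  )
}

DENOM_TOL <- 1e-9
D_ROUND_THRESHOLD <- -0.002

#' Closed-form decomposition, no-cue (d1 = d2) variant
#'
#' Solves the forward model for the deterministic proportion and the two
#' stochastic rates under the fixed-determinism assumption `d = d1 = d2`:
#' \deqn{d = (P12 - P1 P2) / (1 - P1 - P2 + P12)}
#' \deqn{s1 = (P1 - P12) / (1 - P2)}
#' \deqn{s2 = (P2 - P12) / (1 - P1)}
#'
#' Sampling noise can push the estimate of `d` slightly negative: values in
#' `[-0.002, 0)` are rounded to 0 and flagged (`rounded_d`); a participant
#' with `d < -0.002` is flagged excluded (`d_below_threshold`). Degenerate
#' denominators (within 1e-9 of zero) flag `degenerate_denominator`.
#' Estimates are never silently clipped, so recovery studies see the raw
#' estimator.
#'
#' @param rates Tibble with columns `P1`, `P2`, `P12` (e.g. from
#'   [compute_rates()]); extra columns pass through.
#' @return The input with columns `d`, `s1`, `s2`, `rounded_d`, `excluded`,
#'   `exclusion_reason` added.
#' @examples
#' solve_nocue(compose_rates(d1 = 0.05, s1 = 0.12, s2 = 0.08))
#' @export
solve_nocue <- function(rates) {
  stopifnot(all(c("P1", "P2", "P12") %in% names(rates)))
  out <- rates |>
    dplyr::mutate(
      .denom = 1 - .data$P1 - .data$P2 + .data$P12,
      .degenerate = abs(.data$.denom) < DENOM_TOL |
        abs(1 - .data$P1) < DENOM_TOL | abs(1 - .data$P2) < DENOM_TOL,
      d = dplyr::if_else(.data$.degenerate, NA_real_,
                         (.data$P12 - .data$P1 * .data$P2) / .data$.denom),
      s1 = dplyr::if_else(.data$.degenerate, NA_real_,
                          (.data$P1 - .data$P12) / (1 - .data$P2)),
      s2 = dplyr::if_else(.data$.degenerate, NA_real_,
                          (.data$P2 - .data$P12) / (1 - .data$P1)),
      rounded_d = !.data$.degenerate & .data$d < 0 &
        .data$d >= D_ROUND_THRESHOLD,
      d = dplyr::if_else(.data$rounded_d, 0, .data$d),
      exclusion_reason = dplyr::case_when(
        .data$.degenerate ~ "degenerate_denominator",
        .data$d < D_ROUND_THRESHOLD ~ "d_below_threshold",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(.data$exclusion_reason)
    ) |>
    dplyr::select(!dplyr::all_of(c(".denom", ".degenerate")))
  out
}

#' Closed-form decomposition, cued-second-pass variant
#'
#' When the second copy is cued, the fixed-determinism assumption is dropped
#' (the cue may convert unfindable displays, so `d2 <= d1` is the hypothesis
#' under test, not a constraint). `s2` and `d2` remain uniquely determined:
#' \deqn{s2 = (P2 - P12) / (1 - P1)}
#' \deqn{d2 = (P12 - P1 P2) / (1 - P1 - P2 + P12)}
#' `d1` is not identifiable from the cued rates alone; it is borrowed from
#' the same participant's uncued decomposition (`d1_ref`), since
#' deterministic errors persist when nothing intervenes. Then
#' \deqn{s1 = (P1 - d1) / (1 - d1).}
#' If the borrowed `d1` overestimates the cued set's true determinism, `s1`
#' can come out negative; such participants are flagged excluded
#' (`negative_s1`).
#'
#' @param rates Tibble with `P1`, `P2`, `P12` for the cued condition.
#' @param d1_ref Reference deterministic proportion(s), recycled over rows —
#'   each participant's `d` from [solve_nocue()] on their uncued condition.
#' @return The input with `d1`, `d2`, `s1`, `s2`, `excluded`,
#'   `exclusion_reason` added.
#' @export
solve_cue <- function(rates, d1_ref) {
  stopifnot(all(c("P1", "P2", "P12") %in% names(rates)))
  d1_ref <- rep_len(as.numeric(d1_ref), nrow(rates))
  out <- rates |>
    dplyr::mutate(
      d1 = d1_ref,
      .denom = 1 - .data$P1 - .data$P2 + .data$P12,
      .degenerate = abs(.data$.denom) < DENOM_TOL |
        abs(1 - .data$P1) < DENOM_TOL | abs(1 - .data$d1) < DENOM_TOL |
        .data$d1 > 1,
      d2 = dplyr::if_else(.data$.degenerate, NA_real_,
                          (.data$P12 - .data$P1 * .data$P2) / .data$.denom),
      s2 = dplyr::if_else(.data$.degenerate, NA_real_,
                          (.data$P2 - .data$P12) / (1 - .data$P1)),
      s1 = dplyr::if_else(.data$.degenerate, NA_real_,
                          (.data$P1 - .data$d1) / (1 - .data$d1)),
      exclusion_reason = dplyr::case_when(
        .data$.degenerate ~ "degenerate_denominator",
        .data$s1 < 0 ~ "negative_s1",
        TRUE ~ NA_character_
      ),
      excluded = !is.na(.data$exclusion_reason)
    ) |>
    dplyr::select(!dplyr::all_of(c(".denom", ".degenerate")))
  out
}

#' Stochastic and deterministic predictions for P12
#'
#' Given observed `P1` and `P2`, purely stochastic errors predict
#' `P12 = P1 * P2` while purely deterministic errors predict
#' `P12 = min(P1, P2)`; any mixture lies between the two.
#'
#' @param rates Tibble with `P1` and `P2` columns.
#' @return The input with `stoch_pred` and `det_pred` columns added.
#' @export
predictions <- function(rates) {
  rates |>
    dplyr::mutate(stoch_pred = .data$P1 * .data$P2,
                  det_pred = pmin(.data$P1, .data$P2))
}

#' Miss rates stratified by absolute target-background contrast
#'
#' Partitions the surviving target-present pairs by |T-B| and computes
#' (P1, P2, P12) per stratum, the split behind the low-versus-high-contrast
#' decomposition comparison. With the default `threshold = 30` the
#' controlled-contrast levels fall into low = {±15} and
#' high = {±45, ±75, ±105}. Pass `breaks` instead for multi-bin stratification
#' of continuous contrasts.
#'
#' @param trials Paired trial tibble carrying `tb_contrast`.
#' @param threshold Two-stratum cut on |T-B| (low: |T-B| < threshold).
#' @param breaks Optional numeric breaks on |T-B| overriding `threshold`.
#' @return [compute_rates()] output with a `contrast_stratum` column.
#' @export
split_by_contrast <- function(trials, threshold = 30, breaks = NULL) {
  stopifnot("tb_contrast" %in% names(trials))
  present <- trials |>
    dplyr::filter(.data$target_present) |>
    dplyr::filter(!is.na(.data$tb_contrast))
  if (nrow(present) == 0) {
    abort("No target-present trials with contrast values.")
  }
  strat <- if (is.null(breaks)) {
    ifelse(abs(present$tb_contrast) < threshold, "low", "high")
  } else {
    as.character(cut(abs(present$tb_contrast), breaks = breaks,
                     include.lowest = TRUE))
  }
  present$contrast_stratum <- strat
  dropped <- is.na(strat)
  if (any(dropped)) {
    warn(sprintf("%d trial(s) outside the contrast bins were omitted.",
                 sum(dropped)))
    present <- present[!dropped, ]
  }
  compute_rates(present, condition = "contrast_stratum")
}

#' Per-participant decomposition for a whole cohort
#'
#' Convenience wrapper running the complete estimation stage on a paired
#' trial log: computes rates per participant (per `cue_group` for cued
#' designs), attaches the stochastic/deterministic predictions, solves the
#' no-cue system for uncued conditions, and — when a `noCue-Cue` condition is
#' present — solves the cued system using each participant's own uncued `d`
#' as `d1_ref` (set `group_d1_ref = TRUE` to borrow the cohort mean instead).
#'
#' @param trials Paired trial tibble.
#' @param group_d1_ref Use the cohort mean uncued `d` (rather than each
#'   participant's own) as the cued-condition reference.
#' @return Estimates tibble: one row per participant x condition with rates,
#'   predictions, `d`/`d1`/`d2`/`s1`/`s2` and exclusion flags. Condition is
#'   `"noCue-noCue"` / `"noCue-Cue"` (or `"all"` when the design has no cue
#'   grouping).
#' @export
decompose_cohort <- function(trials, group_d1_ref = FALSE) {
  has_cue <- "cue_group" %in% names(trials) &&
    any(trials$cue_group == "noCue-Cue")
  if (!has_cue) {
    rates <- compute_rates(trials)
    est <- solve_nocue(predictions(rates))
    est$condition <- "all"
    return(dplyr::relocate(est, "condition", .after = "participant_id"))
  }
  rates <- compute_rates(trials, condition = "cue_group")
  nocue <- rates |>
    dplyr::filter(.data$cue_group == "noCue-noCue") |>
    predictions() |>
    solve_nocue() |>
    dplyr::mutate(d1 = .data$d, d2 = .data$d)
  cued_rates <- rates |>
    dplyr::filter(.data$cue_group == "noCue-Cue") |>
    predictions()
  ref <- if (group_d1_ref) {
    rep(mean(nocue$d[!nocue$excluded], na.rm = TRUE), nrow(cued_rates))
  } else {
    nocue$d[match(cued_rates$participant_id, nocue$participant_id)]
  }
  cued <- solve_cue(cued_rates, d1_ref = ref)
  dplyr::bind_rows(nocue, cued) |>
    dplyr::rename(condition = "cue_group") |>
    dplyr::arrange(.data$participant_id, .data$condition)
}
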