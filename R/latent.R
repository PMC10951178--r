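#' Latent error parameters for the four-state trial model
#'
#' A target-present display is either fundamentally *unfindable* (it will be
#' missed with certainty — the source of deterministic errors) or *findable*.
#' Findable targets are still missed stochastically with per-round
#' probabilities `s1` and `s2`. Unfindability is drawn once per display and
#' persists across the two copies; a findable display can never become
#' unfindable. When the second copy is cued, a `d2 < d1` fraction of
#' unfindable displays converts to findable, which is how a cueing
#' intervention can reduce deterministic errors.
#'
#' Under this model the expected observed rates are
#' \deqn{P1 = d1(1-s1) + s1}
#' \deqn{P2 = d2 + s2(d1-d2) + (1-d1)s2}
#' \deqn{P12 = d2 + s2(d1-d2) + s1(1-d1)s2}
#'
#' @param d1 Proportion of target-present displays unfindable in round 1
#'   (0-1).
#' @param d2 Proportion unfindable on *cued* second copies (0 <= d2 <= d1).
#'   On uncued second copies unfindability always persists (effective
#'   d2 = d1). Defaults to `d1` (no cue effect).
#' @param s1,s2 Stochastic miss probabilities in rounds 1 and 2 (0-1).
#' @param fa_rate False-alarm probability on target-absent trials (0-1).
#' @param contrast_link Optional `c(threshold, slope)`: makes per-display
#'   unfindability a decreasing logistic function of absolute
#'   target-background contrast,
#'   `d1 * plogis((threshold - |T-B|) / slope)`, emulating that low-contrast
#'   targets drive deterministic errors. Displays without a contrast value use
#'   `d1` unchanged.
#' @return A `latent_params` list.
#' @examples
#' latent_params(d1 = 0.05, s1 = 0.12, s2 = 0.08)
#' @export
latent_params <- function(d1 = 0.05, d2 = d1, s1 = 0.12, s2 = 0.08,
                          fa_rate = 0.01, contrast_link = NULL) {
  vals <- c(d1 = d1, d2 = d2, s1 = s1, s2 = s2, fa_rate = fa_rate)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    abort("All latent rates must lie in [0, 1].")
  }
  if (d2 > d1) {
    abort("`d2` must not exceed `d1`: findable displays cannot become unfindable.")
  }
  if (!is.null(contrast_link)) {
    stopifnot(is.numeric(contrast_link), length(contrast_link) == 2,
              contrast_link[2] > 0)
    contrast_link <- stats::setNames(as.numeric(contrast_link),
                                     c("threshold", "slope"))
  }
  structure(list(d1 = d1, d2 = d2, s1 = s1, s2 = s2, fa_rate = fa_rate,
                 contrast_link = contrast_link),
            class = "latent_params")
}

#' @export
print.latent_params <- function(x, ...) {
  cat(sprintf(
    "<latent_params: d1 = %.3g, d2 = %.3g, s1 = %.3g, s2 = %.3g, fa = %.3g%s>\n",
    x$d1, x$d2, x$s1, x$s2, x$fa_rate,
    if (is.null(x$contrast_link)) "" else
      sprintf(", contrast link (thr %.3g, slope %.3g)",
              x$contrast_link["threshold"], x$contrast_link["slope"])))
  invisible(x)
}

#' Reaction-time generator for simulated trials
#'
#' A lognormal RT law per design cell, present so the exclusion pipeline
#' (extreme screen, 2.5-SD trim, motor-correction removal) has realistic
#' material to act on. Cell medians follow ordinary search phenomenology —
#' slower target-absent responses, a positive set-size slope, a second-pass
#' speed-up on absent trials — and none of the defaults is an empirical claim.
#'
#' @param median_present_ms,median_absent_ms Median RT at set size 18.
#' @param slope_present_ms,slope_absent_ms Added median ms per additional
#'   display item.
#' @param repeat_speedup_absent Multiplier on absent-trial medians for the
#'   second copy (< 1 means faster).
#' @param sdlog Lognormal shape parameter.
#' @param outlier_rate Probability a trial's RT is multiplied by 10 (injected
#'   extreme responses).
#' @param correction_rate Probability a trial is flagged motor-corrected.
#' @return An `rt_model` list.
#' @export
rt_model <- function(median_present_ms = 1200, median_absent_ms = 1900,
                     slope_present_ms = 40, slope_absent_ms = 80,
                     repeat_speedup_absent = 0.85, sdlog = 0.4,
                     outlier_rate = 0.005, correction_rate = 0.01) {
  stopifnot(median_present_ms > 0, median_absent_ms > 0, sdlog > 0,
            outlier_rate >= 0, outlier_rate <= 1,
            correction_rate >= 0, correction_rate <= 1,
            repeat_speedup_absent > 0)
  structure(list(median_present_ms = median_present_ms,
                 median_absent_ms = median_absent_ms,
                 slope_present_ms = slope_present_ms,
                 slope_absent_ms = slope_absent_ms,
                 repeat_speedup_absent = repeat_speedup_absent,
                 sdlog = sdlog, outlier_rate = outlier_rate,
                 correction_rate = correction_rate),
            class = "rt_model")
}
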