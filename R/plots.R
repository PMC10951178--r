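#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed P12 against the stochastic and deterministic predictions
#'
#' One point per participant at `(P1, P12)` (solid), with the stochastic
#' prediction `P1 * P2` and deterministic prediction `min(P1, P2)` as open
#' markers, faceted by condition when more than one is present.
#'
#' @param object A `p12_table` from [scatter_p12()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot p12_table
#' @export
autoplot.p12_table <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(c("P12", "stoch_pred", "det_pred")),
                        names_to = "quantity", values_to = "value") |>
    dplyr::mutate(quantity = factor(
      .data$quantity, levels = c("P12", "stoch_pred", "det_pred"),
      labels = c("observed P12", "stochastic P1*P2",
                 "deterministic min(P1, P2)")))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$P1, y = .data$value,
                                          color = .data$quantity,
                                          shape = .data$quantity)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey50") +
    ggplot2::scale_color_manual(values = c("observed P12" = "blue",
                                           "stochastic P1*P2" = "red",
                                           "deterministic min(P1, P2)" =
                                             "black")) +
    ggplot2::scale_shape_manual(values = c("observed P12" = 16,
                                           "stochastic P1*P2" = 1,
                                           "deterministic min(P1, P2)" = 1)) +
    ggplot2::labs(x = "P1 (miss rate, first appearance)", y = "P12",
                  color = NULL, shape = NULL) +
    ggplot2::theme_minimal()
  if ("condition" %in% names(object) &&
      dplyr::n_distinct(object$condition) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}

#' Plot hit rate against target-background contrast
#'
#' @param object A `binned_hit_rates` table from [bin_hit_rates()].
#' @param ... Ignored.
#' @return A ggplot object with +/- 1 SEM error bars.
#' @method autoplot binned_hit_rates
#' @export
autoplot.binned_hit_rates <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$tb_center, y = .data$hit_rate)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$hit_rate - .data$sem,
                                        ymax = .data$hit_rate + .data$sem),
                           width = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "T-B contrast", y = "Hit rate") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Bar plot of solved error parameters with SEM error bars
#'
#' Cohort means of the deterministic proportion and the round-wise
#' stochastic rates (excluded participants omitted), the standard companion
#' to the P12 scatter.
#'
#' @param estimates Estimates tibble from [decompose_cohort()] /
#'   [solve_nocue()].
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates) {
  params <- intersect(c("d", "d1", "d2", "s1", "s2"), names(estimates))
  long <- estimates |>
    dplyr::filter(!.data$excluded) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  grouping <- intersect("condition", names(long))
  summ <- long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "parameter")))) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$parameter,
                                          y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = "Estimated proportion") +
    ggplot2::theme_minimal()
  if (length(grouping) && dplyr::n_distinct(summ$condition) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$condition))
  }
  p
}
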