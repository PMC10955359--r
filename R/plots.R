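#' Histogram of raters' gender-specific beliefs
#'
#' The belief-heterogeneity figure: distributions of raters' beliefs about
#' male and female players' round-1 Split propensity.
#'
#' @param raters A rater tibble.
#' @param binwidth Histogram bin width in percentage points.
#' @return A ggplot object.
#' @export
plot_belief_distribution <- function(raters, binwidth = 5) {
  long <- raters %>%
    select("rater_id", "belief_male", "belief_female") %>%
    tidyr::pivot_longer(
      c("belief_male", "belief_female"),
      names_to = "target_gender", names_prefix = "belief_",
      values_to = "belief"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$belief)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(~target_gender, ncol = 1) +
    ggplot2::labs(
      x = "Belief: % of players choosing Split in round 1",
      y = "Raters"
    ) +
    ggplot2::theme_minimal()
}

#' Mean signal-detection accuracy by treatment and round
#'
#' The headline accuracy figure: per-treatment means of per-rater accuracy
#' `Z(H) - Z(1 - R)` for first- and second-impression guesses, with the
#' chance level at zero.
#'
#' @param sdt_summary A per-rater summary from [sdt_summarise()].
#' @param raters A rater tibble (for treatment labels).
#' @return A ggplot object.
#' @export
plot_accuracy_by_treatment <- function(sdt_summary, raters) {
  df <- sdt_summary %>%
    left_join(select(raters, "rater_id", "treatment"), by = "rater_id") %>%
    group_by(.data$treatment, .data$round) %>%
    summarise(mean_accuracy = mean(.data$accuracy), .groups = "drop") %>%
    mutate(round = factor(.data$round, labels = c("Round 1", "Round 2")))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$treatment, y = .data$mean_accuracy, fill = .data$round)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Accuracy, Z(H) - Z(1 - R)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_accuracy_by_treatment
#' @param object A `coop_study` from [run_study()].
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.coop_study <- function(object, ...) {
  plot_accuracy_by_treatment(object$sdt_summary, object$raters_kept)
}

#' Plot a parameter-recovery report
#'
#' Point estimates with 95% percentile-bootstrap intervals; generating values
#' (when known) are drawn as open circles.
#'
#' @param object A `coop_recovery` from [recover_parameters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coop_recovery <- function(object, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$parameter)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.2
    ) +
    ggplot2::geom_point(size = 2)
  if (any(!is.na(df$truth))) {
    gg <- gg + ggplot2::geom_point(
      ggplot2::aes(x = .data$truth), shape = 1, size = 3, na.rm = TRUE
    )
  }
  gg + ggplot2::labs(x = "Estimate (95% bootstrap interval)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
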