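#' Cooperator and cheater detection rates
#'
#' For one rater's guesses in one round: `H`, the proportion of correct
#' guesses among players whose true choice was Split (cooperator detection
#' rate), and `R`, the proportion correct among players whose true choice was
#' Take All (cheater detection rate). A rate whose truth class is empty is
#' undefined and reported as `NA`.
#'
#' @param guesses A guess tibble (columns `guess`, `truth`, `correct`) for a
#'   single rater-round.
#' @return A one-row tibble: `n_split_truth`, `n_take_truth`, `H`, `R`.
#' @examples
#' detection_rates(tibble::tibble(
#'   guess = c("Split", "TakeAll", "TakeAll", "TakeAll"),
#'   truth = c("Split", "Split", "TakeAll", "TakeAll"),
#'   correct = c(1L, 0L, 1L, 1L)
#' ))
#' @export
detection_rates <- function(guesses) {
  if (nrow(guesses) == 0) abort("Cannot compute detection rates on no guesses.")
  is_split <- guesses$truth == "Split"
  n_s <- sum(is_split)
  n_t <- sum(!is_split)
  tibble(
    n_split_truth = n_s,
    n_take_truth = n_t,
    H = if (n_s > 0) mean(guesses$correct[is_split]) else NA_real_,
    R = if (n_t > 0) mean(guesses$correct[!is_split]) else NA_real_
  )
}

#' Clamp a detection rate away from 0 and 1
#'
#' Rates of zero become 1/100,000 and rates of one become 99,999/100,000 so
#' that inverse-normal z-scores stay finite; interior rates are unchanged.
#'
#' @param rate Numeric vector of rates in \[0, 1\].
#' @return Clamped rates.
#' @examples
#' clamp_rate(c(0, 0.598, 1))
#' @export
clamp_rate <- function(rate) {
  ok <- is.na(rate) | (rate >= 0 & rate <= 1)
  if (!all(ok)) abort("Rates must lie in [0, 1].")
  dplyr::case_when(
    rate == 0 ~ 1e-5,
    rate == 1 ~ 1 - 1e-5,
    .default = rate
  )
}

#' Signal-detection accuracy
#'
#' `Z(H) - Z(1 - R)` on clamped rates, where `Z` is the standard-normal
#' quantile function. Zero means no demonstrable ability to distinguish
#' cooperators from cheaters; clamping keeps degenerate guessers finite (an
#' all-Split guesser has `H = 1`, `R = 0` and accuracy exactly 0).
#'
#' @param H,R Cooperator and cheater detection rates in \[0, 1\]; vectorized.
#' @return Accuracy in z-units.
#' @examples
#' sdt_accuracy(0.598, 0.448)
#' @export
sdt_accuracy <- function(H, R) {
  qnorm(clamp_rate(H)) - qnorm(1 - clamp_rate(R))
}

#' Signal-detection bias
#'
#' `-0.5 * (Z(H) + Z(1 - R))` on clamped rates: negative values are a
#' tendency to guess Split, positive values a tendency to guess Take All,
#' independent of discrimination ability.
#'
#' @inheritParams sdt_accuracy
#' @return Bias in z-units.
#' @examples
#' sdt_bias(0.9, 0.1) # Split-leaning, negative
#' @export
sdt_bias <- function(H, R) {
  -0.5 * (qnorm(clamp_rate(H)) + qnorm(1 - clamp_rate(R)))
}

#' Percent of guesses that are correct
#'
#' @param guesses A guess tibble with a `correct` column (0/1).
#' @return Percentage in \[0, 100\].
#' @export
correctness <- function(guesses) {
  if (nrow(guesses) == 0) abort("Cannot compute correctness on no guesses.")
  100 * mean(guesses$correct)
}

#' Odds ratio of guess against truth
#'
#' Cross-product ratio of the 2x2 guess-by-truth table (hits x correct
#' rejections over misses x false alarms), with the Haldane-Anscombe +0.5
#' continuity correction applied to every cell whenever any cell is zero.
#'
#' @param hits Split guesses on Split truths.
#' @param misses Take All guesses on Split truths.
#' @param false_alarms Split guesses on Take All truths.
#' @param correct_rejections Take All guesses on Take All truths.
#' @return A positive odds ratio.
#' @examples
#' odds_ratio(20, 5, 5, 20)
#' odds_ratio(10, 0, 0, 10) # corrected: 441
#' @export
odds_ratio <- function(hits, misses, false_alarms, correct_rejections) {
  cells <- c(hits, misses, false_alarms, correct_rejections)
  if (any(cells < 0)) abort("Cell counts must be nonnegative.")
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

#' Belief-accuracy measures for one gender belief
#'
#' Signed error (belief minus the gender's actual round-1 Split percentage),
#' absolute error, and the sufficiently-correct dummy: 1 if the belief is at
#' least 50% about a majority-cooperative gender, or below 50% about a
#' majority-non-cooperative gender; otherwise 0.
#'
#' @param belief Belief percentage(s) in \[0, 100\]; vectorized.
#' @param actual_rate Actual Split percentage(s) of the gender.
#' @param majority_cooperative Logical: did players of this gender tend to
#'   cooperate?
#' @return A tibble with `signed_error`, `absolute_error`,
#'   `sufficiently_correct`.
#' @examples
#' belief_error_measures(44.2, 61.4, TRUE)
#' @export
belief_error_measures <- function(belief, actual_rate, majority_cooperative) {
  if (any(belief < 0 | belief > 100) || any(actual_rate < 0 | actual_rate > 100)) {
    abort("Percentages must be in [0, 100].")
  }
  signed <- belief - actual_rate
  tibble(
    signed_error = signed,
    absolute_error = abs(signed),
    sufficiently_correct = as.integer(
      (belief >= 50 & majority_cooperative) | (belief < 50 & !majority_cooperative)
    )
  )
}

#' Per-rater, per-round signal-detection summary
#'
#' Computes detection rates, clamped-rate accuracy and bias, correctness and
#' the guess-truth odds ratio for every rater-round, each from that rater's
#' full set of guesses in the round (never from pooled rates). Raters with an
#' undefined rate (a truth class absent from the round) get `NA` accuracy and
#' bias with a warning; this cannot occur at the default calibration, where
#' both choices are present among the 94 players.
#'
#' @param guesses A guess tibble from [simulate_rating_study()].
#' @return A tibble with one row per rater-round: `rater_id`, `round`,
#'   `n_split_truth`, `n_take_truth`, `H`, `R`, `accuracy`, `bias`,
#'   `correctness`, `odds_ratio`.
#' @export
sdt_summarise <- function(guesses) {
  out <- guesses %>%
    group_by(.data$rater_id, .data$round) %>%
    summarise(
      n_split_truth = sum(.data$truth == "Split"),
      n_take_truth = sum(.data$truth == "TakeAll"),
      H = ifelse(.data$n_split_truth[1] > 0,
                 mean(.data$correct[.data$truth == "Split"]), NA_real_),
      R = ifelse(.data$n_take_truth[1] > 0,
                 mean(.data$correct[.data$truth == "TakeAll"]), NA_real_),
      correctness = 100 * mean(.data$correct),
      hits = sum(.data$guess == "Split" & .data$truth == "Split"),
      misses = sum(.data$guess == "TakeAll" & .data$truth == "Split"),
      false_alarms = sum(.data$guess == "Split" & .data$truth == "TakeAll"),
      correct_rejections = sum(.data$guess == "TakeAll" & .data$truth == "TakeAll"),
      .groups = "drop"
    ) %>%
    mutate(
      accuracy = sdt_accuracy(.data$H, .data$R),
      bias = sdt_bias(.data$H, .data$R),
      odds_ratio = purrr::pmap_dbl(
        list(.data$hits, .data$misses, .data$false_alarms, .data$correct_rejections),
        odds_ratio
      )
    ) %>%
    select(
      "rater_id", "round", "n_split_truth", "n_take_truth", "H", "R",
      "accuracy", "bias", "correctness", "odds_ratio"
    )
  if (anyNA(out$H) || anyNA(out$R)) {
    warn("Some rater-rounds have an undefined detection rate (empty truth class); their accuracy/bias are NA.")
  }
  out
}

#' Evaluate raters' gender beliefs against realized cooperation
#'
#' Compares each rater's two gender-specific beliefs with the corresponding
#' genders' realized round-1 Split percentages from the simulated matches.
#'
#' @param raters A rater tibble.
#' @param players A player tibble.
#' @param matches A match tibble.
#' @return A tibble with one row per rater and target gender: `rater_id`,
#'   `target_gender`, `belief`, `actual`, `signed_error`, `absolute_error`,
#'   `sufficiently_correct`.
#' @export
beliefs_eval <- function(raters, players, matches) {
  truths <- player_truths(matches) %>%
    left_join(select(players, "player_id", "gender"), by = "player_id")
  actual <- truths %>%
    group_by(.data$gender) %>%
    summarise(actual = 100 * mean(.data$own_r1 == "Split"), .groups = "drop")
  long <- raters %>%
    select("rater_id", "belief_male", "belief_female") %>%
    tidyr::pivot_longer(
      c("belief_male", "belief_female"),
      names_to = "target_gender", names_prefix = "belief_",
      values_to = "belief"
    ) %>%
    left_join(actual, by = c(target_gender = "gender"))
  bind_rows(
    long %>%
      mutate(belief_error_measures(.data$belief, .data$actual, .data$actual >= 50))
  )
}
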