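#' Payment schedule for belief statements and guesses
#'
#' Beliefs are paid by a quadratic scoring rule that only pays within a
#' stated error window (1/6 of the scale by default); each correct binary
#' guess earns a flat amount.
#'
#' @param max_belief_payment Payment at zero belief error, per belief (USD).
#' @param per_correct_guess Payment per correct guess (USD).
#' @param qsr_window Error window as a fraction of the 0-1 scale; payments
#'   are zero at and beyond it.
#' @return A list of class `coop_payment_schedule`.
#' @export
payment_schedule <- function(max_belief_payment = 0.50,
                             per_correct_guess = 0.02,
                             qsr_window = 1 / 6) {
  if (max_belief_payment < 0 || per_correct_guess < 0) {
    abort("Payments must be nonnegative.")
  }
  if (qsr_window <= 0 || qsr_window > 1) abort("`qsr_window` must be in (0, 1].")
  structure(
    list(
      max_belief_payment = max_belief_payment,
      per_correct_guess = per_correct_guess,
      qsr_window = qsr_window
    ),
    class = "coop_payment_schedule"
  )
}

#' Quadratic-scoring-rule payment for a belief statement
#'
#' With `d = |belief - actual| / 100`, pays
#' `max_belief_payment * (1 - (d / qsr_window)^2)` when `d` is inside the
#' window and nothing otherwise: maximal at zero error, falling continuously
#' to zero at the window boundary.
#'
#' @param belief,actual Percentages in \[0, 100\]; vectorized.
#' @param schedule A [payment_schedule()].
#' @return Payment(s) in USD.
#' @examples
#' quadratic_belief_payment(50, 50, payment_schedule(max_belief_payment = 1))
#' @export
quadratic_belief_payment <- function(belief, actual,
                                     schedule = payment_schedule()) {
  if (any(belief < 0 | belief > 100) || any(actual < 0 | actual > 100)) {
    abort("Percentages must be in [0, 100].")
  }
  d <- abs(belief - actual) / 100
  ifelse(
    d <= schedule$qsr_window,
    schedule$max_belief_payment * (1 - (d / schedule$qsr_window)^2),
    0
  )
}

#' Flat payment for correct guesses
#'
#' @param n_correct Number of correct guesses; vectorized.
#' @param schedule A [payment_schedule()].
#' @return Payment(s) in USD.
#' @export
guess_payment <- function(n_correct, schedule = payment_schedule()) {
  if (any(n_correct < 0)) abort("`n_correct` must be nonnegative.")
  n_correct * schedule$per_correct_guess
}

#' Per-rater payout table
#'
#' Combines the quadratic-scoring payments for the two gender beliefs
#' (evaluated against realized gender cooperation rates) with the flat
#' payment for correct guesses across both rounds.
#'
#' @param raters A rater tibble.
#' @param guesses A guess tibble.
#' @param beliefs A belief-evaluation tibble from [beliefs_eval()].
#' @param schedule A [payment_schedule()].
#' @return A tibble: `rater_id`, `belief_payment_male`,
#'   `belief_payment_female`, `guess_payment`, `total`.
#' @export
compute_payouts <- function(raters, guesses, beliefs,
                            schedule = payment_schedule()) {
  belief_pay <- beliefs %>%
    mutate(pay = quadratic_belief_payment(.data$belief, .data$actual, schedule)) %>%
    select("rater_id", "target_gender", "pay") %>%
    tidyr::pivot_wider(
      names_from = "target_gender", values_from = "pay",
      names_prefix = "belief_payment_"
    )
  guess_pay <- guesses %>%
    group_by(.data$rater_id) %>%
    summarise(n_correct = sum(.data$correct), .groups = "drop") %>%
    mutate(guess_payment = guess_payment(.data$n_correct, schedule))
  raters %>%
    select("rater_id") %>%
    left_join(belief_pay, by = "rater_id") %>%
    left_join(select(guess_pay, "rater_id", "guess_payment"), by = "rater_id") %>%
    mutate(total = .data$belief_payment_male + .data$belief_payment_female +
             .data$guess_payment)
}
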