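#' Game configuration for the Split-or-Take-All repeated Prisoner's Dilemma
#'
#' Bundles the payoff matrix, the random-stopping rule, the cohort composition
#' and the behavioural-law parameters of the player study. Defaults reproduce
#' the study conditions: a 94-player cohort (44 men, 50 women), payoffs of
#' $5/$5 for mutual Split, $0/$10 for unilateral Take All and $0/$0 for mutual
#' Take All, continuation probability `stopping_base^(1 - n)` from round `n`
#' with two rounds guaranteed, and gender-specific conditional-cooperator
#' shares of 61.4% (men) and 86.0% (women); at these defaults the expected
#' overall conditional-cooperator share is 74.5%.
#'
#' @param payoff_mutual_split Payment to each player when both Split (USD).
#' @param payoff_sucker Payment to a Split player whose partner Takes All.
#' @param payoff_temptation Payment to a Take All player whose partner Splits.
#' @param payoff_mutual_take Payment to each player when both Take All.
#' @param stopping_base Base of the random-stopping rule; continuation from
#'   round `n` has probability `stopping_base^(1 - n)`.
#' @param min_rounds Guaranteed number of rounds (the design fixes 2).
#' @param max_rounds_cap Hard truncation of match length; at the default base
#'   the probability of ever reaching it is negligible.
#' @param n_male,n_female Cohort composition.
#' @param p_coop_male,p_coop_female Probability that a male/female player is a
#'   conditional cooperator (rather than a non-cooperator).
#' @param tremble Symmetric execution-error probability: each round the
#'   realized choice flips the intended one with this probability. Must be
#'   below 0.5.
#' @return A list of class `coop_game_config`.
#' @examples
#' cfg <- game_config()
#' expected_round1_split(cfg)
#' @export
game_config <- function(payoff_mutual_split = 5,
                        payoff_sucker = 0,
                        payoff_temptation = 10,
                        payoff_mutual_take = 0,
                        stopping_base = 4,
                        min_rounds = 2L,
                        max_rounds_cap = 10L,
                        n_male = 44L,
                        n_female = 50L,
                        p_coop_male = 0.614,
                        p_coop_female = 0.860,
                        tremble = 0.05) {
  if (!(payoff_temptation > payoff_mutual_split &&
        payoff_mutual_split > payoff_mutual_take)) {
    abort("Payoffs must satisfy temptation > mutual split > mutual take.")
  }
  if (payoff_sucker != payoff_mutual_take) {
    abort("The sucker payoff must equal the mutual Take All payoff.")
  }
  if (stopping_base <= 1) abort("`stopping_base` must exceed 1.")
  if (min_rounds != 2L) abort("The design guarantees exactly 2 rounds minimum.")
  if (tremble < 0 || tremble >= 0.5) abort("`tremble` must be in [0, 0.5).")
  if (p_coop_male < 0 || p_coop_male > 1 || p_coop_female < 0 || p_coop_female > 1) {
    abort("Cooperator-type probabilities must be in [0, 1].")
  }
  structure(
    list(
      payoff_mutual_split = payoff_mutual_split,
      payoff_sucker = payoff_sucker,
      payoff_temptation = payoff_temptation,
      payoff_mutual_take = payoff_mutual_take,
      stopping_base = stopping_base,
      min_rounds = as.integer(min_rounds),
      max_rounds_cap = as.integer(max_rounds_cap),
      n_male = as.integer(n_male),
      n_female = as.integer(n_female),
      p_coop_male = p_coop_male,
      p_coop_female = p_coop_female,
      tremble = tremble
    ),
    class = "coop_game_config"
  )
}

#' Round payoffs of the Split-or-Take-All game
#'
#' Maps a pair of choices to the pair of dollar payoffs: mutual Split pays
#' $5 each, a lone Take All pays $10 against $0, and mutual Take All pays
#' nothing. Vectorized over rounds.
#'
#' @param a,b Character vectors of `"Split"`/`"TakeAll"` choices for the two
#'   players.
#' @param config A [game_config()].
#' @return A tibble with columns `pay_a` and `pay_b` (USD), one row per round.
#' @examples
#' pd_payoff("Split", "TakeAll")
#' @export
pd_payoff <- function(a, b, config = game_config()) {
  assert_choice(a)
  assert_choice(b)
  one_side <- function(own, other) {
    dplyr::case_when(
      own == "Split" & other == "Split" ~ config$payoff_mutual_split,
      own == "Split" & other == "TakeAll" ~ config$payoff_sucker,
      own == "TakeAll" & other == "Split" ~ config$payoff_temptation,
      .default = config$payoff_mutual_take
    )
  }
  tibble(pay_a = one_side(a, b), pay_b = one_side(b, a))
}

#' Continuation probability of the random-stopping rule
#'
#' From current round `n` the match continues to another round with
#' probability `base^(1 - n)`: 1, 1/4, 1/16, 1/64 for rounds 1-4 at the
#' default base of 4, so a second round is always reached.
#'
#' @param n Current round index (>= 1); vectorized.
#' @param base Stopping-rule base (> 1).
#' @return Numeric vector of probabilities in (0, 1].
#' @examples
#' continuation_probability(1:4)
#' @export
continuation_probability <- function(n, base = 4) {
  if (any(n < 1)) abort("Round index `n` must be >= 1.")
  if (base <= 1) abort("`base` must exceed 1.")
  base^(1 - n)
}

#' Sample match lengths under the random-stopping rule
#'
#' Draws one uniform variate per completed round: from round `n` the match
#' continues with probability `base^(1 - n)`, truncated at
#' `config$max_rounds_cap`. Round 1 always continues, so every match has at
#' least two rounds and `P(L = 2) = 1 - 1/base`.
#'
#' @param n_matches Number of lengths to draw.
#' @param config A [game_config()].
#' @return Integer vector of match lengths, all >= 2.
#' @examples
#' set.seed(1)
#' table(sample_match_length(1000))
#' @export
sample_match_length <- function(n_matches, config = game_config()) {
  vapply(seq_len(n_matches), function(i) {
    len <- 1L
    while (len < config$max_rounds_cap &&
           runif(1) < continuation_probability(len, config$stopping_base)) {
      len <- len + 1L
    }
    len
  }, integer(1))
}

#' Generate a synthetic player cohort
#'
#' Each male player is a conditional cooperator with probability
#' `p_coop_male`, each female with `p_coop_female`; the remainder are
#' non-cooperators. The default cohort has 94 players (44 men, 50 women),
#' the unique composition under which the calibrated gender-specific
#' cooperator shares and the 74.5% overall share are exact count ratios
#' (27/44, 43/50, 70/94).
#'
#' @param config A [game_config()].
#' @return A tibble with columns `player_id`, `gender` (`"male"`/`"female"`),
#'   `ptype` (`"conditional_cooperator"`/`"non_cooperator"`) and `tremble`.
#' @examples
#' set.seed(1)
#' generate_players()
#' @export
generate_players <- function(config = game_config()) {
  n <- config$n_male + config$n_female
  if (n %% 2L != 0L) {
    abort("Total player count must be even so that all players can be paired.")
  }
  gender <- c(rep("male", config$n_male), rep("female", config$n_female))
  p_coop <- ifelse(gender == "male", config$p_coop_male, config$p_coop_female)
  tibble(
    player_id = seq_len(n),
    gender = gender,
    ptype = ifelse(runif(n) < p_coop, "conditional_cooperator", "non_cooperator"),
    tremble = config$tremble
  )
}

#' Behavioural law: one player's choice in one round
#'
#' The conditional-cooperation heuristic: a non-cooperator always intends
#' Take All; a conditional cooperator intends Split in round 1 and thereafter
#' copies the partner's previous realized choice (tit-for-tat). The realized
#' choice flips the intended one with probability `tremble`. Vectorized.
#'
#' @param ptype Character vector of player types.
#' @param partner_prev Partner's previous-round realized choice, or `NA` in
#'   round 1.
#' @param tremble Execution-error probability (scalar or vector).
#' @return Character vector of realized choices.
#' @examples
#' round_choice("conditional_cooperator", NA, 0)
#' round_choice("conditional_cooperator", "TakeAll", 0)
#' @export
round_choice <- function(ptype, partner_prev, tremble = 0) {
  if (!all(ptype %in% c("conditional_cooperator", "non_cooperator"))) {
    abort("`ptype` must be 'conditional_cooperator' or 'non_cooperator'.")
  }
  intended <- intended_choice(ptype, partner_prev)
  n <- length(intended)
  flip <- runif(n) < tremble
  ifelse(flip, ifelse(intended == "Split", "TakeAll", "Split"), intended)
}

# Deterministic part of the behavioural law (no tremble).
intended_choice <- function(ptype, partner_prev) {
  ifelse(
    ptype == "non_cooperator",
    "TakeAll",
    ifelse(is.na(partner_prev), "Split", partner_prev)
  )
}

#' Simulate matched-pair game histories
#'
#' Pairs the cohort by a uniform random perfect matching (gender-blind),
#' samples each pair's length under the stopping rule and plays out every
#' round under the conditional-cooperation law with trembles, filling in
#' payoffs round-wise.
#'
#' @param players A player tibble from [generate_players()].
#' @param config A [game_config()].
#' @return A tibble with one row per match-round: `match_id`, `id_a`, `id_b`,
#'   `round`, `choice_a`, `choice_b`, `pay_a`, `pay_b`.
#' @examples
#' set.seed(1)
#' simulate_matches(generate_players())
#' @export
simulate_matches <- function(players, config = game_config()) {
  n <- nrow(players)
  if (n %% 2L != 0L) abort("Cannot pair an odd number of players.")
  perm <- sample(players$player_id)
  n_pair <- n %/% 2L
  id_a <- perm[seq_len(n_pair)]
  id_b <- perm[n_pair + seq_len(n_pair)]
  lengths <- sample_match_length(n_pair, config)
  type_of <- stats::setNames(players$ptype, players$player_id)
  trem_of <- stats::setNames(players$tremble, players$player_id)

  purrr::map_dfr(seq_len(n_pair), function(m) {
    ta <- type_of[[as.character(id_a[m])]]
    tb <- type_of[[as.character(id_b[m])]]
    tra <- trem_of[[as.character(id_a[m])]]
    trb <- trem_of[[as.character(id_b[m])]]
    len <- lengths[m]
    ca <- character(len)
    cb <- character(len)
    prev_a <- NA_character_
    prev_b <- NA_character_
    for (r in seq_len(len)) {
      ca[r] <- round_choice(ta, prev_b, tra)
      cb[r] <- round_choice(tb, prev_a, trb)
      prev_a <- ca[r]
      prev_b <- cb[r]
    }
    pays <- pd_payoff(ca, cb, config)
    tibble(
      match_id = m, id_a = id_a[m], id_b = id_b[m], round = seq_len(len),
      choice_a = ca, choice_b = cb, pay_a = pays$pay_a, pay_b = pays$pay_b
    )
  })
}

#' Four-way behavioural-history category of a round-1 outcome
#'
#' Classifies the ordered pair (own round-1 choice, partner round-1 choice)
#' from the focal player's perspective into the four categories used to break
#' out second-impression guesses: Both Take All, Take All/Partner Split,
#' Split/Partner Take All, Both Split.
#'
#' @param own_r1,partner_r1 Character vectors of `"Split"`/`"TakeAll"`.
#' @return Character vector with values `"both_take"`, `"take_partner_split"`,
#'   `"split_partner_take"`, `"both_split"`.
#' @examples
#' history_category("TakeAll", "Split")
#' @export
history_category <- function(own_r1, partner_r1) {
  assert_choice(own_r1)
  assert_choice(partner_r1)
  dplyr::case_when(
    own_r1 == "TakeAll" & partner_r1 == "TakeAll" ~ "both_take",
    own_r1 == "TakeAll" & partner_r1 == "Split" ~ "take_partner_split",
    own_r1 == "Split" & partner_r1 == "TakeAll" ~ "split_partner_take",
    .default = "both_split"
  )
}

#' Per-player view of the simulated matches
#'
#' Reshapes a match table into one row per player with own and partner
#' round-1 and round-2 realized choices plus the behavioural-history
#' category — the player-level truths that raters guess about.
#'
#' @param matches A match tibble from [simulate_matches()].
#' @return A tibble with columns `player_id`, `partner_id`, `own_r1`,
#'   `partner_r1`, `own_r2`, `history`.
#' @export
player_truths <- function(matches) {
  r1 <- filter(matches, .data$round == 1L)
  r2 <- filter(matches, .data$round == 2L)
  a <- tibble(
    player_id = r1$id_a, partner_id = r1$id_b,
    own_r1 = r1$choice_a, partner_r1 = r1$choice_b,
    own_r2 = r2$choice_a[match(r1$match_id, r2$match_id)]
  )
  b <- tibble(
    player_id = r1$id_b, partner_id = r1$id_a,
    own_r1 = r1$choice_b, partner_r1 = r1$choice_a,
    own_r2 = r2$choice_b[match(r1$match_id, r2$match_id)]
  )
  bind_rows(a, b) %>%
    mutate(history = history_category(.data$own_r1, .data$partner_r1)) %>%
    arrange(.data$player_id)
}

#' Expected round-1 intended cooperation share of a cohort
#'
#' The gender-weighted mean conditional-cooperator share,
#' `(n_male * p_coop_male + n_female * p_coop_female) / (n_male + n_female)`.
#' This is the expected share of *intended* round-1 Split choices; realized
#' shares are additionally perturbed by the tremble
#' (`p + tremble - 2 * p * tremble`).
#'
#' @param config A [game_config()].
#' @return A proportion in \[0, 1\].
#' @examples
#' expected_round1_split(game_config())
#' @export
expected_round1_split <- function(config = game_config()) {
  (config$n_male * config$p_coop_male + config$n_female * config$p_coop_female) /
    (config$n_male + config$n_female)
}
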