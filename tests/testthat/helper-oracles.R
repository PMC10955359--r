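# Independent inverse-normal oracle: bisection on the normal CDF, never
# touching qnorm(). Used to cross-check the signal-detection z-scores.
bisect_inv_norm <- function(p, lo = -40, hi = 40, tol = 1e-12) {
  stopifnot(p > 0, p < 1)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Brute-force oracle for the random-stopping rule: sequential continuation
# draws, used to cross-check sample_match_length's closed-form distribution.
oracle_match_length <- function(n, base = 4, cap = 10) {
  vapply(seq_len(n), function(i) {
    len <- 1L
    while (len < cap && runif(1) < base^(1 - len)) len <- len + 1L
    len
  }, integer(1))
}

# A deterministic two-player cohort with prescribed types.
two_players <- function(type_a, type_b, tremble = 0) {
  tibble::tibble(
    player_id = 1:2,
    gender = c("male", "female"),
    ptype = c(type_a, type_b),
    tremble = tremble
  )
}

# A small but full study for pipeline-level tests: defaults everywhere,
# light inference settings.
small_run_config <- function(seed = 1L) {
  run_config(seed = seed, n_perm = 999L, n_boot = 50L)
}

# Simulated cohort pieces without the inference stages.
simulate_cohort <- function(seed, game = game_config(), rater = rater_config()) {
  set.seed(seed)
  players <- generate_players(game)
  matches <- simulate_matches(players, game)
  kept <- apply_exclusions(generate_raters(rater), rater$min_duration_s)$kept
  guesses <- simulate_rating_study(players, matches, kept, rater)
  list(players = players, matches = matches, raters = kept, guesses = guesses)
}
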