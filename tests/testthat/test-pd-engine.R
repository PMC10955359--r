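test_that("payoff matrix matches the game's stakes, cell by cell", {
  expect_equal(pd_payoff("Split", "Split"), tibble::tibble(pay_a = 5, pay_b = 5))
  expect_equal(pd_payoff("Split", "TakeAll"), tibble::tibble(pay_a = 0, pay_b = 10))
  expect_equal(pd_payoff("TakeAll", "Split"), tibble::tibble(pay_a = 10, pay_b = 0))
  expect_equal(pd_payoff("TakeAll", "TakeAll"), tibble::tibble(pay_a = 0, pay_b = 0))
  expect_error(pd_payoff("Steal", "Split"), "Split")
})

test_that("payoffs are anti-symmetric and Take All weakly dominates", {
  cells <- tidyr::expand_grid(a = c("Split", "TakeAll"), b = c("Split", "TakeAll"))
  fwd <- pd_payoff(cells$a, cells$b)
  rev <- pd_payoff(cells$b, cells$a)
  expect_equal(fwd$pay_a, rev$pay_b)
  expect_equal(fwd$pay_b, rev$pay_a)
  # against either opponent choice, Take All does at least as well as Split,
  # strictly better against Split
  for (opp in c("Split", "TakeAll")) {
    p_take <- pd_payoff("TakeAll", opp)$pay_a
    p_split <- pd_payoff("Split", opp)$pay_a
    expect_gte(p_take, p_split)
  }
  expect_gt(pd_payoff("TakeAll", "Split")$pay_a, pd_payoff("Split", "Split")$pay_a)
  # total stake is 10 unless both defect
  expect_equal(fwd$pay_a + fwd$pay_b, c(10, 10, 10, 0))
})

test_that("continuation probability follows the 4^(1-n) stopping rule", {
  expect_equal(continuation_probability(1:4), c(1, 1 / 4, 1 / 16, 1 / 64))
  expect_true(all(diff(continuation_probability(1:10)) < 0))
  expect_equal(continuation_probability(1), 1) # round 2 always reached
  expect_error(continuation_probability(0), "n")
  expect_error(continuation_probability(2, base = 1), "base")
})

test_that("match lengths come from sequential stopping draws", {
  set.seed(101)
  draws <- sample_match_length(1e5)
  expect_true(all(draws >= 2))
  # closed form: P(L = 2) = 1 - 1/4, P(L >= 4) = 1/4 * 1/16
  expect_equal(mean(draws == 2), 0.75, tolerance = 0.01)
  expect_equal(mean(draws >= 4), 1 / 64, tolerance = 0.15)
  # brute-force sequential-draw oracle agrees on the whole distribution
  set.seed(102)
  oracle <- oracle_match_length(1e5)
  expect_equal(mean(draws == 3), mean(oracle == 3), tolerance = 0.05)
  expect_equal(mean(draws), mean(oracle), tolerance = 0.01)
  expect_true(all(draws <= game_config()$max_rounds_cap))
})

test_that("player generation respects cohort composition and type rates", {
  set.seed(7)
  pl <- generate_players()
  expect_equal(nrow(pl), 94)
  expect_equal(sum(pl$gender == "male"), 44)
  expect_equal(sum(pl$gender == "female"), 50)
  expect_false(anyDuplicated(pl$player_id) > 0)

  all_cc <- generate_players(game_config(p_coop_male = 1, p_coop_female = 1))
  expect_true(all(all_cc$ptype == "conditional_cooperator"))

  # binomial mean at scale: male type share converges to p_coop_male
  set.seed(8)
  big <- generate_players(game_config(n_male = 5e4, n_female = 5e4))
  share <- mean(big$ptype[big$gender == "male"] == "conditional_cooperator")
  expect_equal(share, 0.614, tolerance = 0.01)

  expect_error(
    generate_players(game_config(n_male = 3, n_female = 4)),
    "paired"
  )
})

test_that("the conditional-cooperation law reproduces its full truth table", {
  cases <- tibble::tribble(
    ~ptype, ~partner_prev, ~expected,
    "conditional_cooperator", NA_character_, "Split",
    "conditional_cooperator", "Split", "Split",
    "conditional_cooperator", "TakeAll", "TakeAll",
    "non_cooperator", NA_character_, "TakeAll",
    "non_cooperator", "Split", "TakeAll",
    "non_cooperator", "TakeAll", "TakeAll"
  )
  got <- round_choice(cases$ptype, cases$partner_prev, tremble = 0)
  expect_equal(got, cases$expected)
  expect_error(round_choice("altruist", NA, 0), "ptype")
})

test_that("trembles flip the intended choice at the stated rate", {
  set.seed(11)
  out <- round_choice(rep("non_cooperator", 2e4), NA_character_, tremble = 0.05)
  expect_equal(mean(out == "Split"), 0.05, tolerance = 0.15)
})

test_that("noise-free matches are the deterministic type-pair trajectories", {
  # all four type pairs, enumerated closed form
  trajectories <- list(
    list(types = c("conditional_cooperator", "conditional_cooperator"),
         a = "Split", b = "Split"),
    list(types = c("non_cooperator", "non_cooperator"),
         a = "TakeAll", b = "TakeAll")
  )
  for (tr in trajectories) {
    set.seed(21)
    m <- simulate_matches(two_players(tr$types[1], tr$types[2]), game_config())
    expect_true(all(m$choice_a == tr$a))
    expect_true(all(m$choice_b == tr$b))
  }
  # mixed pair: the cooperator splits once, is exploited, then defects forever
  set.seed(22)
  m <- simulate_matches(
    two_players("conditional_cooperator", "non_cooperator"),
    game_config()
  )
  cc_col <- if (m$id_a[1] == 1) "choice_a" else "choice_b"
  nc_col <- setdiff(c("choice_a", "choice_b"), cc_col)
  expect_equal(m[[cc_col]], c("Split", rep("TakeAll", nrow(m) - 1)))
  expect_true(all(m[[nc_col]] == "TakeAll"))
})

test_that("simulated matches partition the cohort and price every round", {
  set.seed(31)
  pl <- generate_players()
  m <- simulate_matches(pl, game_config())
  expect_equal(dplyr::n_distinct(m$match_id), 47)
  ids <- unique(c(m$id_a, m$id_b))
  expect_setequal(ids, pl$player_id)
  # payoffs are the payoff operation applied round-wise
  pays <- pd_payoff(m$choice_a, m$choice_b)
  expect_equal(m$pay_a, pays$pay_a)
  expect_equal(m$pay_b, pays$pay_b)
  expect_true(all(table(m$match_id) >= 2))
  expect_error(simulate_matches(pl[-1, ], game_config()), "odd|pair")
})

test_that("round-2 cooperation is exactly the tit-for-tat recount when noise-free", {
  cfg <- game_config(tremble = 0)
  for (seed in 41:43) {
    set.seed(seed)
    pl <- generate_players(cfg)
    m <- simulate_matches(pl, cfg)
    tr <- player_truths(m)
    tr <- dplyr::left_join(tr, pl[, c("player_id", "ptype")], by = "player_id")
    expected_r2 <- ifelse(
      tr$ptype == "non_cooperator", "TakeAll", tr$partner_r1
    )
    expect_equal(tr$own_r2, expected_r2)
  }
})

test_that("behavioural history categories cover the four round-1 outcomes", {
  expect_equal(history_category("Split", "Split"), "both_split")
  expect_equal(history_category("TakeAll", "Split"), "take_partner_split")
  expect_equal(history_category("Split", "TakeAll"), "split_partner_take")
  expect_equal(history_category("TakeAll", "TakeAll"), "both_take")
})

test_that("the calibrated cohort tracks the observed round-2 cooperation rate", {
  set.seed(51)
  r2 <- replicate(200, {
    pl <- generate_players()
    tr <- player_truths(simulate_matches(pl, game_config()))
    mean(tr$own_r2 == "Split")
  })
  expect_lt(abs(mean(100 * r2) - 53.2), 3)
})

test_that("game configuration enforces the payoff ordering and tremble bounds", {
  expect_error(game_config(payoff_temptation = 4), "temptation")
  expect_error(game_config(payoff_sucker = 1), "sucker")
  expect_error(game_config(tremble = 0.6), "tremble")
  expect_error(game_config(min_rounds = 3), "2 rounds")
  expect_equal(expected_round1_split(game_config()), 0.7448, tolerance = 1e-3)
})
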