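test_that("belief pairs honour their bivariate moments up to clipping", {
  set.seed(61)
  bp <- draw_belief_pairs(1e5, 44.2, 63.9, 20, 20, 0.503)
  expect_true(all(bp$belief_male >= 0 & bp$belief_male <= 100))
  # clipped-normal mean oracle: E[min(max(X,0),100)] in closed form
  clip_mean <- function(mu, sd) {
    a <- (0 - mu) / sd
    b <- (100 - mu) / sd
    100 * pnorm(-b) + mu * (pnorm(b) - pnorm(a)) - sd * (dnorm(b) - dnorm(a))
  }
  expect_equal(mean(bp$belief_male), clip_mean(44.2, 20), tolerance = 0.01)
  expect_equal(mean(bp$belief_female), clip_mean(63.9, 20), tolerance = 0.01)
  expect_equal(cor(bp$belief_male, bp$belief_female), 0.503, tolerance = 0.05)

  set.seed(62)
  indep <- draw_belief_pairs(1e5, 50, 50, 15, 15, 0)
  expect_equal(cor(indep$belief_male, indep$belief_female), 0, tolerance = 0.02)

  degen <- draw_belief_pairs(10, 44.2, 63.9, 1e-9, 1e-9, 0.5)
  expect_equal(degen$belief_male, rep(44.2, 10), tolerance = 1e-6)
  expect_error(draw_belief_pairs(5, 50, 50, -1, 20, 0), "sds")
  expect_error(draw_belief_pairs(5, 50, 50, 20, 20, 1.2), "rho")
})

test_that("the unknown-gender prior is the plain average of gender beliefs", {
  expect_equal(belief_about_players(44.2, 63.9), 54.05)
  expect_equal(belief_about_players(50, 50), 50)
  expect_equal(belief_about_players(0, 100), 50)
})

test_that("appearance cues match the truth at their stated validity", {
  expect_equal(sample_appearance_cue(rep("Split", 10), 1), rep("Split", 10))
  set.seed(71)
  cues <- sample_appearance_cue(rep("Split", 1e5), 0.75)
  expect_equal(mean(cues == "Split"), 0.75, tolerance = 0.01)
  set.seed(72)
  chance <- sample_appearance_cue(rep("TakeAll", 1e5), 0.5)
  expect_equal(mean(chance == "TakeAll"), 0.5, tolerance = 0.01)
  expect_error(sample_appearance_cue("Split", 0.4), "validity")
})

test_that("cue updating is a log-odds shift of the stated size", {
  expect_equal(combine_belief_and_cue(63.9, NA, 0.75, 1), 63.9)
  expect_equal(combine_belief_and_cue(50, "Split", 0.75, 1), 75)
  # arithmetic oracle for a Take All cue on an interior prior
  expected <- 100 * plogis(qlogis(0.442) - log(0.6 / 0.4))
  expect_equal(combine_belief_and_cue(44.2, "TakeAll", 0.6, 1), expected)
  # extreme priors are clipped before the update, so output stays finite
  expect_lt(combine_belief_and_cue(100, "TakeAll", 0.9, 5), 100)
  expect_gt(combine_belief_and_cue(0, "Split", 0.9, 5), 0)
  # zero weight ignores the cue
  expect_equal(combine_belief_and_cue(63.9, "TakeAll", 0.9, 0), 63.9)
})

test_that("information sets grow monotonically across treatments", {
  player <- list(gender = "female")
  truths <- list(own_r1 = "Split", partner_r1 = "TakeAll")
  none <- build_information_set("none", player, truths, 1)
  expect_false(none$shows_gender)
  expect_null(none$cue)
  expect_null(none$history)
  label <- build_information_set("label", player, truths, 1)
  expect_true(label$shows_gender)
  expect_equal(label$gender, "female")
  expect_null(label$cue)
  set.seed(81)
  video <- build_information_set("video", player, truths, 2)
  expect_true(video$shows_gender)
  expect_true(video$cue %in% c("Split", "TakeAll"))
  expect_equal(video$history, list(own_r1 = "Split", partner_r1 = "TakeAll"))
  photo <- build_information_set("photo", player, truths, 1)
  expect_null(photo$history) # no history before round 2
  expect_error(build_information_set("none", player, truths, 3), "round")
})

test_that("round-1 guessing mixes threshold and probability-matching strategies", {
  rater <- list(
    belief_male = 40, belief_female = 87.8, lambda_optimize = 1, cue_weight = 1
  )
  info <- list(shows_gender = FALSE, gender = NULL, cue = NULL,
               cue_validity = NULL, history = NULL)
  # threshold rater with posterior 63.9 always predicts cooperation
  expect_equal(unique(replicate(20, guess_round1(rater, info))), "Split")
  # a tie at exactly 50 goes to Split
  tie <- list(belief_male = 50, belief_female = 50, lambda_optimize = 1,
              cue_weight = 1)
  expect_equal(unique(replicate(20, guess_round1(tie, info))), "Split")
  # probability matching reproduces the posterior as a long-run rate
  set.seed(91)
  pm <- list(belief_male = 54, belief_female = 54, lambda_optimize = 0,
             cue_weight = 1)
  draws <- replicate(5e3, guess_round1(pm, info))
  expect_equal(mean(draws == "Split"), 0.54, tolerance = 0.03)
})

test_that("round-2 guessing follows the heuristic at full adherence", {
  rater <- list(belief_male = 50, belief_female = 50, lambda_optimize = 1,
                cue_weight = 1, heuristic_adherence = 1)
  info_for <- function(own, partner) {
    list(shows_gender = FALSE, gender = NULL, cue = NULL, cue_validity = NULL,
         history = list(own_r1 = own, partner_r1 = partner))
  }
  expect_equal(guess_round2(rater, info_for("Split", "Split")), "Split")
  expect_equal(guess_round2(rater, info_for("Split", "TakeAll")), "TakeAll")
  expect_equal(guess_round2(rater, info_for("TakeAll", "Split")), "TakeAll")
  expect_equal(guess_round2(rater, info_for("TakeAll", "TakeAll")), "TakeAll")
  no_hist <- list(shows_gender = FALSE, gender = NULL, cue = NULL,
                  cue_validity = NULL, history = NULL)
  expect_error(guess_round2(rater, no_hist), "history")
})

test_that("the recruited cohort carries the exact exclusion fixture", {
  set.seed(101)
  rt <- generate_raters()
  expect_equal(nrow(rt), 445)
  expect_equal(sum(rt$flag_small_screen), 11)
  expect_equal(sum(!rt$flag_small_screen & rt$duration_s < 480), 12)
  res <- apply_exclusions(rt)
  expect_equal(nrow(res$kept), 422)
  expect_equal(res$audit$n[res$audit$rule == "small_screen"], 11)
  expect_equal(res$audit$n[res$audit$rule == "too_fast"], 12)
  expect_equal(
    as.vector(table(res$kept$treatment)[c("none", "label", "photo", "video")]),
    c(108L, 101L, 108L, 105L)
  )
})

test_that("exclusions conserve counts for arbitrary flag patterns", {
  set.seed(102)
  for (i in 1:5) {
    rt <- generate_raters()
    rt$flag_small_screen <- runif(nrow(rt)) < runif(1)
    rt$duration_s <- runif(nrow(rt), 100, 2000)
    res <- apply_exclusions(rt)
    expect_equal(sum(res$audit$n), nrow(rt))
    expect_equal(res$audit$n[res$audit$rule == "kept"], nrow(res$kept))
  }
  clean <- generate_raters(rater_config(n_small_screen = 0, n_fast = 0))
  expect_equal(nrow(apply_exclusions(clean)$kept), nrow(clean))
  all_flagged <- clean
  all_flagged$flag_small_screen <- TRUE
  res <- apply_exclusions(all_flagged)
  expect_equal(nrow(res$kept), 0)
  expect_equal(sum(res$audit$n), nrow(clean))
})

test_that("the rating study produces one record per rater, player and round", {
  co <- simulate_cohort(111)
  expect_equal(nrow(co$guesses), 422 * 94 * 2)
  counts <- dplyr::count(co$guesses, rater_id, round)
  expect_true(all(counts$n == 94))
  expect_equal(co$guesses$correct, as.integer(co$guesses$guess == co$guesses$truth))
})

test_that("unanimity raters guess Split for every first impression", {
  set.seed(121)
  pl <- generate_players()
  m <- simulate_matches(pl, game_config())
  rt <- apply_exclusions(generate_raters())$kept
  rt$belief_male <- 100
  rt$belief_female <- 100
  rt$lambda_optimize <- 1
  g <- simulate_rating_study(pl, m, rt, rater_config())
  expect_true(all(g$guess[g$round == 1] == "Split"))
})

test_that("full heuristic adherence is perfectly correct in a noise-free world", {
  cfg <- game_config(tremble = 0)
  set.seed(131)
  pl <- generate_players(cfg)
  m <- simulate_matches(pl, cfg)
  rt <- apply_exclusions(generate_raters())$kept
  rt$heuristic_adherence <- 1
  g <- simulate_rating_study(pl, m, rt, rater_config())
  expect_equal(mean(g$correct[g$round == 2]), 1)
})

test_that("probability-matching raters converge on their effective prior", {
  # lambda = 0, no cue: long-run Split-guess rate equals the prior
  set.seed(141)
  pl <- generate_players()
  m <- simulate_matches(pl, game_config())
  rt <- apply_exclusions(generate_raters())$kept
  rt <- rt[rt$treatment == "none", ][rep(1, 30), ]
  rt$rater_id <- seq_len(nrow(rt))
  rt$belief_male <- 40
  rt$belief_female <- 70
  rt$lambda_optimize <- 0
  g <- simulate_rating_study(pl, m, rt, rater_config())
  rate <- mean(g$guess[g$round == 1] == "Split")
  expect_equal(rate, 0.55, tolerance = 0.03) # prior = (40 + 70) / 2
})
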