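#' Configuration of the synthetic rater cohort
#'
#' Parameters of the rating study: arm sizes of the four information
#' treatments (post-exclusion), the exclusion fixture, the correlated
#' gender-specific belief distribution by rater gender, and the guess-strategy
#' parameters. Defaults reproduce the study conditions: arms of 108 (None),
#' 101 (Label), 108 (Photo) and 105 (Video) raters remaining after excluding
#' 11 small-screen and 12 too-fast participants from 445 recruits; mean
#' beliefs about male/female players of 46.3/61.8 (male raters), 42.2/66.5
#' (female raters) and 44.2/63.9 otherwise, with correlation 0.503.
#'
#' @param n_none,n_label,n_photo,n_video Raters per treatment after
#'   exclusions.
#' @param n_small_screen,n_fast Exclusion fixture: additional recruits flagged
#'   for small-screen use and for sub-threshold completion time (disjoint by
#'   construction).
#' @param p_rater_male,p_rater_female Rater gender shares; the remainder
#'   identify as neither.
#' @param belief_means Named list of `c(belief_male, belief_female)` mean
#'   percentages keyed by rater gender (`male`, `female`, `other`).
#' @param belief_sd Common standard deviation of both gender beliefs
#'   (percentage points; the source tables do not pin it, so it is a free
#'   parameter).
#' @param belief_rho Correlation between a rater's two gender beliefs.
#' @param lambda_optimize Mixture weight on the optimising (threshold)
#'   strategy; the complement probability-matches.
#' @param cue_weight Log-odds weight on the appearance cue.
#' @param heuristic_adherence Probability that a round-2 guess follows the
#'   conditional-cooperation heuristic rather than the round-1 rule.
#' @param cue_validity_photo,cue_validity_video Probability that the
#'   appearance cue matches the player's round-1 choice (>= 0.5; equal by
#'   default, reflecting the null photo-vs-video accuracy contrast).
#' @param min_duration_s Completion-time exclusion threshold in seconds.
#' @return A list of class `coop_rater_config`.
#' @export
rater_config <- function(n_none = 108L, n_label = 101L, n_photo = 108L,
                         n_video = 105L,
                         n_small_screen = 11L, n_fast = 12L,
                         p_rater_male = 0.4853, p_rater_female = 0.4898,
                         belief_means = list(
                           male = c(46.3, 61.8),
                           female = c(42.2, 66.5),
                           other = c(44.2, 63.9)
                         ),
                         belief_sd = 20, belief_rho = 0.503,
                         lambda_optimize = 0.7,
                         cue_weight = 1,
                         heuristic_adherence = 0.8,
                         cue_validity_photo = 0.55,
                         cue_validity_video = 0.55,
                         min_duration_s = 480) {
  if (belief_sd <= 0) abort("`belief_sd` must be positive.")
  if (abs(belief_rho) >= 1) abort("`belief_rho` must lie in (-1, 1).")
  for (p in c(lambda_optimize, heuristic_adherence)) {
    if (p < 0 || p > 1) abort("Strategy probabilities must be in [0, 1].")
  }
  for (v in c(cue_validity_photo, cue_validity_video)) {
    if (v < 0.5 || v > 1) {
      abort("Cue validities must be in [0.5, 1]; anti-diagnostic cues are not modelled.")
    }
  }
  structure(
    list(
      n_none = as.integer(n_none), n_label = as.integer(n_label),
      n_photo = as.integer(n_photo), n_video = as.integer(n_video),
      n_small_screen = as.integer(n_small_screen), n_fast = as.integer(n_fast),
      p_rater_male = p_rater_male, p_rater_female = p_rater_female,
      belief_means = belief_means,
      belief_sd = belief_sd, belief_rho = belief_rho,
      lambda_optimize = lambda_optimize, cue_weight = cue_weight,
      heuristic_adherence = heuristic_adherence,
      cue_validity_photo = cue_validity_photo,
      cue_validity_video = cue_validity_video,
      min_duration_s = min_duration_s
    ),
    class = "coop_rater_config"
  )
}

#' Draw correlated gender-specific belief pairs
#'
#' Samples (belief about male players, belief about female players) pairs
#' from a bivariate normal with the given means, standard deviations and
#' correlation, then clips to the elicitable 0-100% range. The elicited Split
#' and Take-All percentages are complementary, so only the Split percentage
#' is represented.
#'
#' @param n Number of pairs.
#' @param mean_male,mean_female Mean belief percentages.
#' @param sd_male,sd_female Standard deviations (> 0).
#' @param rho Correlation in (-1, 1).
#' @return A tibble with columns `belief_male` and `belief_female`.
#' @examples
#' set.seed(1)
#' draw_belief_pairs(5, 44.2, 63.9, 20, 20, 0.503)
#' @export
draw_belief_pairs <- function(n, mean_male, mean_female, sd_male, sd_female, rho) {
  if (sd_male <= 0 || sd_female <= 0) abort("Belief sds must be positive.")
  if (abs(rho) >= 1) abort("`rho` must lie in (-1, 1).")
  sigma <- matrix(
    c(sd_male^2, rho * sd_male * sd_female,
      rho * sd_male * sd_female, sd_female^2),
    nrow = 2
  )
  draws <- MASS::mvrnorm(n, mu = c(mean_male, mean_female), Sigma = sigma)
  draws <- matrix(pmin(pmax(draws, 0), 100), ncol = 2)
  tibble(belief_male = draws[, 1], belief_female = draws[, 2])
}

#' Belief about players of unknown gender
#'
#' The unweighted mean of a rater's two gender-specific beliefs — the prior
#' they apply to a player whose gender is not revealed.
#'
#' @param belief_male,belief_female Belief percentages; vectorized.
#' @return Numeric vector of percentages.
#' @examples
#' belief_about_players(44.2, 63.9)
#' @export
belief_about_players <- function(belief_male, belief_female) {
  (belief_male + belief_female) / 2
}

#' Sample an appearance cue of stated validity
#'
#' A photo or thin-slice video is modelled as a binary cue that equals the
#' player's true round-1 choice with probability `validity` and the opposite
#' choice otherwise. Validity 0.5 is an uninformative cue.
#'
#' @param truth_r1 True round-1 choice(s), `"Split"`/`"TakeAll"`; vectorized.
#' @param validity Probability the cue matches the truth, in \[0.5, 1\].
#' @return Character vector of cues.
#' @export
sample_appearance_cue <- function(truth_r1, validity) {
  assert_choice(truth_r1)
  if (any(validity < 0.5) || any(validity > 1)) {
    abort("`validity` must be in [0.5, 1].")
  }
  match_truth <- runif(length(truth_r1)) < validity
  ifelse(match_truth, truth_r1,
         ifelse(truth_r1 == "Split", "TakeAll", "Split"))
}

#' Update a prior belief with an appearance cue
#'
#' Bayesian-style log-odds update: the posterior log-odds of Split equal the
#' prior log-odds plus `cue_weight * s * log(validity / (1 - validity))`,
#' where `s` is +1 for a Split cue and -1 for a Take All cue. Priors of 0 or
#' 100 are first clipped to 0.1/99.9 so the log-odds stay finite; an absent
#' cue (`NA`) leaves the prior unchanged.
#'
#' @param prior Prior Split percentage(s) in \[0, 100\]; vectorized.
#' @param cue `"Split"`, `"TakeAll"` or `NA` for no cue.
#' @param validity Cue validity in \[0.5, 1\].
#' @param cue_weight Nonnegative weight on the cue log-likelihood ratio.
#' @return Posterior Split percentage(s).
#' @examples
#' combine_belief_and_cue(50, "Split", 0.75, 1)
#' @export
combine_belief_and_cue <- function(prior, cue, validity, cue_weight = 1) {
  n <- max(length(prior), length(cue), length(validity))
  prior <- rep_len(prior, n)
  cue <- rep_len(cue, n)
  validity <- rep_len(validity, n)
  p <- pmin(pmax(prior, 0.1), 99.9) / 100
  s <- dplyr::case_when(
    is.na(cue) ~ 0,
    cue == "Split" ~ 1,
    cue == "TakeAll" ~ -1
  )
  llr <- ifelse(s == 0, 0, cue_weight * s * log(validity / (1 - validity)))
  lo <- log(p / (1 - p)) + llr
  post <- 100 * stats::plogis(lo)
  ifelse(is.na(cue), prior, post)
}

#' Information set shown to a rater about one player
#'
#' Assembles what a treatment reveals: the None arm shows nothing beyond the
#' player ID; Label adds the gender; Photo and Video add an appearance cue
#' sampled at the arm's validity (gender remains visible). Round-2 guesses
#' additionally see the pair's round-1 behavioural history in every arm.
#'
#' @param treatment One of `"none"`, `"label"`, `"photo"`, `"video"`.
#' @param player One row of a player tibble (needs `gender`).
#' @param truths The player's row of [player_truths()] (needs `own_r1`,
#'   `partner_r1`).
#' @param round Guess round, 1 or 2.
#' @param config A [rater_config()] supplying cue validities.
#' @return A list with fields `shows_gender`, `gender`, `cue`, `cue_validity`,
#'   `history` (`NULL` for round 1).
#' @export
build_information_set <- function(treatment, player, truths, round,
                                  config = rater_config()) {
  if (!round %in% c(1L, 2L)) abort("`round` must be 1 or 2.")
  if (!treatment %in% c("none", "label", "photo", "video")) {
    abort("Unknown treatment.")
  }
  shows_gender <- treatment != "none"
  validity <- switch(treatment,
    photo = config$cue_validity_photo,
    video = config$cue_validity_video,
    NULL
  )
  cue <- if (!is.null(validity)) {
    sample_appearance_cue(truths$own_r1, validity)
  } else {
    NULL
  }
  history <- if (round == 2L) {
    list(own_r1 = truths$own_r1, partner_r1 = truths$partner_r1)
  } else {
    NULL
  }
  list(
    shows_gender = shows_gender,
    gender = if (shows_gender) player$gender else NULL,
    cue = cue,
    cue_validity = validity,
    history = history
  )
}

# Posterior Split percentage a rater assigns to one player, given what the
# treatment reveals. Vectorized over records.
posterior_split_pct <- function(belief_male, belief_female, shows_gender,
                                player_gender, cue, validity, cue_weight) {
  prior <- ifelse(
    shows_gender,
    ifelse(player_gender == "male", belief_male, belief_female),
    belief_about_players(belief_male, belief_female)
  )
  combine_belief_and_cue(prior, cue, validity, cue_weight)
}

# One draw of the round-1 guess rule given a posterior: with probability
# `lambda` use the threshold strategy (Split iff posterior >= 50, ties to
# Split), else probability-match. Vectorized.
draw_round1_guess <- function(posterior, lambda) {
  n <- length(posterior)
  optimise <- runif(n) < lambda
  ifelse(
    optimise,
    ifelse(posterior >= 50, "Split", "TakeAll"),
    ifelse(runif(n) < posterior / 100, "Split", "TakeAll")
  )
}

#' First-impression guess about one player
#'
#' The effective prior is the rater's belief about players of unknown gender
#' when the treatment hides gender, and the gender-specific belief otherwise;
#' an appearance cue, if present, updates it via
#' [combine_belief_and_cue()]. With probability `lambda_optimize` the rater
#' optimises (guesses Split iff the posterior is at least 50%); otherwise
#' they probability-match, guessing Split with probability equal to the
#' posterior.
#'
#' @param rater One row of a rater tibble (needs `belief_male`,
#'   `belief_female`, `lambda_optimize`, `cue_weight`).
#' @param info An information set from [build_information_set()].
#' @return `"Split"` or `"TakeAll"`.
#' @export
guess_round1 <- function(rater, info) {
  post <- posterior_split_pct(
    rater$belief_male, rater$belief_female, info$shows_gender,
    if (info$shows_gender) info$gender else NA_character_,
    if (is.null(info$cue)) NA_character_ else info$cue,
    if (is.null(info$cue_validity)) 0.5 else info$cue_validity,
    rater$cue_weight
  )
  draw_round1_guess(post, rater$lambda_optimize)
}

#' Second-impression guess about one player
#'
#' With probability `heuristic_adherence` the rater applies the
#' conditional-cooperation heuristic to the round-1 history: predict Take All
#' if the player chose Take All in round 1, otherwise predict the player
#' mirrors the partner's round-1 choice. Otherwise the rater falls back to
#' the first-impression rule on the same information set.
#'
#' @inheritParams guess_round1
#' @return `"Split"` or `"TakeAll"`.
#' @export
guess_round2 <- function(rater, info) {
  if (is.null(info$history)) {
    abort("Round-2 guesses require the round-1 behavioural history.")
  }
  heuristic <- heuristic_prediction(info$history$own_r1, info$history$partner_r1)
  if (runif(1) < rater$heuristic_adherence) {
    heuristic
  } else {
    guess_round1(rater, info)
  }
}

# The conditional-cooperation heuristic's round-2 prediction. Vectorized.
heuristic_prediction <- function(own_r1, partner_r1) {
  ifelse(own_r1 == "TakeAll", "TakeAll", partner_r1)
}

#' Generate the synthetic rater cohort, including the exclusion fixture
#'
#' Produces the full recruited cohort: the four treatment arms at their
#' post-exclusion sizes plus `n_small_screen` raters flagged for small-screen
#' use and `n_fast` with sub-threshold completion times (disjoint flags, so
#' the exclusion arithmetic is exact). Rater genders are drawn at the
#' configured shares; each rater's belief pair is drawn from the bivariate
#' normal keyed to their gender via [draw_belief_pairs()].
#'
#' @param config A [rater_config()].
#' @return A tibble with columns `rater_id`, `gender`, `treatment`,
#'   `belief_male`, `belief_female`, `lambda_optimize`, `cue_weight`,
#'   `heuristic_adherence`, `flag_small_screen`, `duration_s`.
#' @examples
#' set.seed(1)
#' nrow(generate_raters())
#' @export
generate_raters <- function(config = rater_config()) {
  kept_treat <- c(
    rep("none", config$n_none), rep("label", config$n_label),
    rep("photo", config$n_photo), rep("video", config$n_video)
  )
  n_excl <- config$n_small_screen + config$n_fast
  excl_treat <- rep(c("none", "label", "photo", "video"), length.out = n_excl)
  treatment <- c(kept_treat, excl_treat)
  n <- length(treatment)

  gender <- sample(
    c("male", "female", "other"), n, replace = TRUE,
    prob = c(config$p_rater_male, config$p_rater_female,
             max(0, 1 - config$p_rater_male - config$p_rater_female))
  )
  beliefs <- matrix(NA_real_, n, 2)
  for (g in c("male", "female", "other")) {
    idx <- which(gender == g)
    if (length(idx) > 0) {
      mu <- config$belief_means[[g]]
      bp <- draw_belief_pairs(
        length(idx), mu[1], mu[2],
        config$belief_sd, config$belief_sd, config$belief_rho
      )
      beliefs[idx, 1] <- bp$belief_male
      beliefs[idx, 2] <- bp$belief_female
    }
  }

  flag_small_screen <- rep(FALSE, n)
  flag_small_screen[length(kept_treat) + seq_len(config$n_small_screen)] <- TRUE
  fast_idx <- length(kept_treat) + config$n_small_screen + seq_len(config$n_fast)
  # kept raters: completion times around the observed 24.4-minute average
  duration_s <- stats::rlnorm(n, meanlog = log(1464), sdlog = 0.35)
  duration_s <- pmax(duration_s, config$min_duration_s)
  duration_s[fast_idx] <- runif(config$n_fast, 120, config$min_duration_s - 1)

  shuffle <- sample.int(n)
  tibble(
    rater_id = seq_len(n),
    gender = gender[shuffle],
    treatment = treatment[shuffle],
    belief_male = beliefs[shuffle, 1],
    belief_female = beliefs[shuffle, 2],
    lambda_optimize = config$lambda_optimize,
    cue_weight = config$cue_weight,
    heuristic_adherence = config$heuristic_adherence,
    flag_small_screen = flag_small_screen[shuffle],
    duration_s = duration_s[shuffle]
  )
}

#' Apply the rater exclusion filter
#'
#' Removes raters flagged for small-screen use, then raters whose completion
#' time falls below the threshold, and reports an audit of counts per rule.
#' Kept plus excluded always equals the input size.
#'
#' @param raters A rater tibble from [generate_raters()].
#' @param min_duration_s Completion-time threshold in seconds.
#' @return A list with elements `kept` (the surviving rater tibble) and
#'   `audit` (a tibble of `rule`, `n_excluded` plus a `total_kept` attribute
#'   row accounting).
#' @examples
#' set.seed(1)
#' apply_exclusions(generate_raters())$audit
#' @export
apply_exclusions <- function(raters, min_duration_s = 480) {
  n0 <- nrow(raters)
  after_screen <- filter(raters, !.data$flag_small_screen)
  n_screen <- n0 - nrow(after_screen)
  kept <- filter(after_screen, .data$duration_s >= min_duration_s)
  n_fast <- nrow(after_screen) - nrow(kept)
  audit <- tibble(
    rule = c("small_screen", "too_fast", "kept"),
    n = c(n_screen, n_fast, nrow(kept))
  )
  stopifnot(sum(audit$n) == n0)
  list(kept = kept, audit = audit)
}

#' Simulate the full rating study
#'
#' Crosses every kept rater with every player and both guess rounds. All
#' round-1 guesses are generated first (first impressions: beliefs plus any
#' appearance cue), then all round-2 guesses (second impressions: the same
#' information plus the pair's round-1 history). Appearance cues are sampled
#' once per rater-player pair and reused in round 2, since the stimulus does
#' not change between rounds. Truths are the players' realized choices from
#' the simulated matches.
#'
#' @param players A player tibble.
#' @param matches A match tibble from [simulate_matches()].
#' @param raters A kept rater tibble (after [apply_exclusions()]).
#' @param config A [rater_config()].
#' @return A guess tibble with `raters x players x 2` rows: `rater_id`,
#'   `player_id`, `round`, `guess`, `truth`, `correct`.
#' @export
simulate_rating_study <- function(players, matches, raters,
                                  config = rater_config()) {
  truths <- player_truths(matches) %>%
    left_join(select(players, "player_id", "gender"), by = "player_id")
  if (anyNA(truths$own_r1) || anyNA(truths$own_r2)) {
    abort("Every player must appear in a match with at least two rounds.")
  }

  nr <- nrow(raters)
  np <- nrow(truths)
  ri <- rep(seq_len(nr), each = np)
  pi <- rep(seq_len(np), times = nr)

  treatment <- raters$treatment[ri]
  shows_gender <- treatment != "none"
  validity <- dplyr::case_when(
    treatment == "photo" ~ config$cue_validity_photo,
    treatment == "video" ~ config$cue_validity_video,
    .default = NA_real_
  )
  has_cue <- !is.na(validity)
  cue <- rep(NA_character_, nr * np)
  if (any(has_cue)) {
    cue[has_cue] <- sample_appearance_cue(
      truths$own_r1[pi[has_cue]], validity[has_cue]
    )
  }
  posterior <- posterior_split_pct(
    raters$belief_male[ri], raters$belief_female[ri],
    shows_gender, truths$gender[pi],
    cue, ifelse(has_cue, validity, 0.5), raters$cue_weight[ri]
  )

  guess_r1 <- draw_round1_guess(posterior, raters$lambda_optimize[ri])

  heuristic <- heuristic_prediction(truths$own_r1[pi], truths$partner_r1[pi])
  adhere <- runif(nr * np) < raters$heuristic_adherence[ri]
  fallback <- draw_round1_guess(posterior, raters$lambda_optimize[ri])
  guess_r2 <- ifelse(adhere, heuristic, fallback)

  bind_rows(
    tibble(
      rater_id = raters$rater_id[ri], player_id = truths$player_id[pi],
      round = 1L, guess = guess_r1, truth = truths$own_r1[pi]
    ),
    tibble(
      rater_id = raters$rater_id[ri], player_id = truths$player_id[pi],
      round = 2L, guess = guess_r2, truth = truths$own_r2[pi]
    )
  ) %>%
    mutate(correct = as.integer(.data$guess == .data$truth))
}
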