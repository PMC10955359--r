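#' Full run configuration
#'
#' Bundles every stage's parameters with the root seed. Child seeds for each
#' stage (players, matches, raters, guesses, inference) are derived
#' deterministically from the root, so a run is reproducible end to end.
#'
#' @param seed Root integer seed.
#' @param game A [game_config()].
#' @param rater A [rater_config()].
#' @param payments A [payment_schedule()].
#' @param n_perm Permutations per test.
#' @param n_boot Bootstrap replicates for parameter recovery.
#' @return A list of class `coop_run_config`.
#' @export
run_config <- function(seed = 1L, game = game_config(), rater = rater_config(),
                       payments = payment_schedule(), n_perm = 10000L,
                       n_boot = 200L) {
  if (n_perm < 999 || n_boot < 1) abort("Invalid inference counts.")
  structure(
    list(
      seed = as.integer(seed), game = game, rater = rater,
      payments = payments, n_perm = as.integer(n_perm),
      n_boot = as.integer(n_boot)
    ),
    class = "coop_run_config"
  )
}

#' Summary tables of guesses by treatment, round and behavioural history
#'
#' Panel A reports, per treatment and round, the percentage of Split guesses,
#' the percentage of correct guesses and the players' actual Split
#' percentage. Panel B breaks round-2 guesses out by the four round-1
#' behavioural-history categories. Percentages are reported to one decimal
#' place.
#'
#' @param guesses A guess tibble.
#' @param matches A match tibble.
#' @param raters A rater tibble.
#' @return A tibble with columns `panel`, `treatment`, `round`, `history`,
#'   `guessed_split_pct`, `correctness_pct`, `actual_split_pct`.
#' @export
summarize_guesses <- function(guesses, matches, raters) {
  g <- guesses %>%
    left_join(select(raters, "rater_id", "treatment"), by = "rater_id")
  cell <- function(df) {
    summarise(
      df,
      guessed_split_pct = round(100 * mean(.data$guess == "Split"), 1),
      correctness_pct = round(100 * mean(.data$correct), 1),
      actual_split_pct = round(100 * mean(.data$truth == "Split"), 1),
      .groups = "drop"
    )
  }
  panel_a <- g %>%
    group_by(.data$treatment, .data$round) %>%
    cell() %>%
    mutate(panel = "A", history = NA_character_)
  hist_tbl <- player_truths(matches) %>% select("player_id", "history")
  panel_b <- g %>%
    filter(.data$round == 2L) %>%
    left_join(hist_tbl, by = "player_id") %>%
    group_by(.data$treatment, .data$round, .data$history) %>%
    cell() %>%
    mutate(panel = "B")
  bind_rows(panel_a, panel_b) %>%
    select(
      "panel", "treatment", "round", "history",
      "guessed_split_pct", "correctness_pct", "actual_split_pct"
    ) %>%
    arrange(.data$panel, .data$treatment, .data$round, .data$history)
}

#' Run the whole study pipeline
#'
#' Simulates the player cohort and matches, generates and filters the rater
#' cohort, simulates both guess rounds, computes the signal-detection and
#' belief-accuracy summaries and payouts, runs the permutation tests and the
#' parameter-recovery harness, and (optionally) writes every table to
#' `output_dir` as UTF-8 header-first CSV plus JSON reports and a manifest.
#' Identical configuration and seed give byte-identical CSV payloads.
#'
#' @param config A [run_config()].
#' @param output_dir Directory for artifacts, created if needed; `NULL`
#'   skips writing.
#' @param quiet Suppress progress messages (which go to standard error).
#' @return Invisibly, a list of class `coop_study` holding all tables:
#'   `players`, `matches`, `raters`, `raters_kept`, `exclusion_audit`,
#'   `guesses`, `sdt_summary`, `beliefs_eval`, `payouts`, `summary_tables`,
#'   `tests`, `recovery`, `config`.
#' @export
run_study <- function(config = run_config(), output_dir = NULL, quiet = FALSE) {
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  say("seed %d", config$seed)
  if (!is.null(output_dir) && !dir.exists(output_dir)) {
    dir.create(output_dir, recursive = TRUE)
    if (!dir.exists(output_dir)) abort("Could not create `output_dir`.")
  }

  set.seed(child_seed(config$seed, "players"))
  players <- generate_players(config$game)
  set.seed(child_seed(config$seed, "matches"))
  matches <- simulate_matches(players, config$game)
  say("players: %d rows; matches: %d rows", nrow(players), nrow(matches))

  set.seed(child_seed(config$seed, "raters"))
  raters <- generate_raters(config$rater)
  excl <- apply_exclusions(raters, config$rater$min_duration_s)
  say(
    "raters: %d recruited, %d kept", nrow(raters), nrow(excl$kept)
  )

  set.seed(child_seed(config$seed, "guesses"))
  guesses <- simulate_rating_study(players, matches, excl$kept, config$rater)
  say("guesses: %d rows", nrow(guesses))

  sdt <- sdt_summarise(guesses)
  beliefs <- beliefs_eval(excl$kept, players, matches)
  payouts <- compute_payouts(excl$kept, guesses, beliefs, config$payments)
  summary_tables <- summarize_guesses(guesses, matches, excl$kept)

  acc <- sdt %>%
    select("rater_id", "round", "accuracy") %>%
    tidyr::pivot_wider(
      names_from = "round", values_from = "accuracy", names_prefix = "r"
    )
  treat_of <- excl$kept$treatment[match(acc$rater_id, excl$kept$rater_id)]
  seed_inf <- child_seed(config$seed, "inference")
  tests <- bind_rows(
    tidy(permutation_sign_test(acc$r1, config$n_perm, seed_inf)) %>%
      mutate(contrast = "round1_accuracy_gt_0"),
    tidy(permutation_sign_test(acc$r2, config$n_perm, seed_inf + 1)) %>%
      mutate(contrast = "round2_accuracy_gt_0"),
    tidy(paired_round_test(acc$r1, acc$r2, config$n_perm, seed_inf + 2)) %>%
      mutate(contrast = "round2_gt_round1_accuracy"),
    tidy(permutation_group_test(acc$r1, treat_of, config$n_perm, seed_inf + 3)) %>%
      mutate(contrast = "round1_accuracy_by_treatment")
  )

  set.seed(child_seed(config$seed, "recovery"))
  recovery <- recover_parameters(
    players, matches, excl$kept, guesses,
    true_values = list(
      p_coop_male = config$game$p_coop_male,
      p_coop_female = config$game$p_coop_female,
      tremble = config$game$tremble,
      lambda_optimize = config$rater$lambda_optimize,
      heuristic_adherence = config$rater$heuristic_adherence
    ),
    n_boot = config$n_boot
  )

  study <- structure(
    list(
      players = players, matches = matches, raters = raters,
      raters_kept = excl$kept, exclusion_audit = excl$audit,
      guesses = guesses, sdt_summary = sdt, beliefs_eval = beliefs,
      payouts = payouts, summary_tables = summary_tables, tests = tests,
      recovery = recovery, config = config
    ),
    class = "coop_study"
  )
  if (!is.null(output_dir)) write_study(study, output_dir, quiet = quiet)
  invisible(study)
}

#' Write every pipeline artifact of a study run
#'
#' @param study A `coop_study` from [run_study()].
#' @param output_dir Target directory.
#' @param quiet Suppress the per-file log.
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, output_dir, quiet = FALSE) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  readr::write_csv(
    select(study$players, "player_id", "gender", "ptype", "tremble"),
    p("players.csv")
  )
  readr::write_csv(study$matches, p("matches.csv"))
  readr::write_csv(study$raters, p("raters.csv"))
  readr::write_csv(
    select(study$guesses, "rater_id", "player_id", "round", "guess",
           "truth", "correct"),
    p("guesses.csv")
  )
  readr::write_csv(study$sdt_summary, p("sdt_summary.csv"))
  readr::write_csv(study$beliefs_eval, p("beliefs_eval.csv"))
  readr::write_csv(study$payouts, p("payouts.csv"))
  readr::write_csv(study$summary_tables, p("summary_tables.csv"))
  jsonlite::write_json(study$tests, p("tests.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    tidy(study$recovery), p("recovery.json"), auto_unbox = TRUE, digits = NA
  )
  manifest <- list(
    seed = study$config$seed,
    package_version = as.character(utils::packageVersion("coopdetect")),
    r_version = R.version.string,
    n_players = nrow(study$players),
    n_raters_recruited = nrow(study$raters),
    n_raters_kept = nrow(study$raters_kept),
    n_guesses = nrow(study$guesses),
    config = list(
      game = unclass(study$config$game),
      rater = unclass(study$config$rater),
      payments = unclass(study$config$payments),
      n_perm = study$config$n_perm,
      n_boot = study$config$n_boot
    )
  )
  jsonlite::write_json(
    manifest, p("run_manifest.json"), auto_unbox = TRUE, digits = NA
  )
  files <- c(
    "players.csv", "matches.csv", "raters.csv", "guesses.csv",
    "sdt_summary.csv", "beliefs_eval.csv", "payouts.csv",
    "summary_tables.csv", "tests.json", "recovery.json", "run_manifest.json"
  )
  if (!quiet) message(sprintf("wrote %d artifacts to %s", length(files), output_dir))
  invisible(file.path(output_dir, files))
}

#' @export
print.coop_study <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<coop_study> seed %d\n  %d players, %d match-rounds, %d/%d raters kept, %d guesses\n",
      "  mean accuracy: round 1 %.3f, round 2 %.3f\n"
    ),
    x$config$seed, nrow(x$players), nrow(x$matches), nrow(x$raters_kept),
    nrow(x$raters), nrow(x$guesses),
    mean(x$sdt_summary$accuracy[x$sdt_summary$round == 1]),
    mean(x$sdt_summary$accuracy[x$sdt_summary$round == 2])
  ))
  invisible(x)
}
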