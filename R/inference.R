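new_perm_test <- function(method, statistic, p_value, n_permutations, seed) {
  structure(
    list(
      method = method, statistic = statistic, p_value = p_value,
      n_permutations = n_permutations, seed = seed
    ),
    class = "coop_perm_test"
  )
}

#' @export
print.coop_perm_test <- function(x, ...) {
  cat(sprintf(
    "Permutation test (%s)\n  statistic = %.4f, p = %.4g (%d permutations)\n",
    x$method, x$statistic, x$p_value, x$n_permutations
  ))
  invisible(x)
}

#' Tidy a permutation test result
#'
#' @param x A `coop_perm_test`.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p_value`,
#'   `n_permutations`, `seed`.
#' @exportS3Method generics::tidy
tidy.coop_perm_test <- function(x, ...) {
  tibble(
    method = x$method, statistic = x$statistic, p_value = x$p_value,
    n_permutations = x$n_permutations, seed = x$seed %||% NA_integer_
  )
}

#' @rdname tidy.coop_perm_test
#' @exportS3Method generics::glance
glance.coop_perm_test <- function(x, ...) tidy(x, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-sample permutation sign test for a positive mean
#'
#' Tests whether per-rater values (for example round accuracies) are centred
#' above zero. The observed statistic is the mean; the null distribution is
#' built by independent random sign flips of each value; the one-sided
#' p-value uses the add-one estimator
#' `(1 + #\{permuted >= observed\}) / (1 + n_perm)`, which can never be zero.
#'
#' @param values Numeric vector (length >= 2).
#' @param n_perm Number of permutations (>= 999).
#' @param seed Optional integer seed for bit-for-bit reproducibility.
#' @return A `coop_perm_test` object; see [tidy.coop_perm_test()].
#' @examples
#' permutation_sign_test(rnorm(50, mean = 0.3), n_perm = 999, seed = 1)
#' @export
permutation_sign_test <- function(values, n_perm = 10000, seed = NULL) {
  if (length(values) < 2) abort("Need at least 2 values.")
  if (n_perm < 999) abort("Use at least 999 permutations.")
  if (!is.null(seed)) set.seed(seed)
  obs <- mean(values)
  n <- length(values)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm)
  perm_means <- as.vector(signs %*% values) / n
  p <- (1 + sum(perm_means >= obs)) / (1 + n_perm)
  new_perm_test("sign-flip mean > 0", obs, p, n_perm, seed)
}

#' Permutation test for differences between groups
#'
#' The observed statistic is the size-weighted between-group sum of squares
#' of group means; the null is built by shuffling group labels. One-sided:
#' large statistics are evidence that group means differ.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length as `values`; at least two
#'   distinct, each nonempty.
#' @inheritParams permutation_sign_test
#' @return A `coop_perm_test` object.
#' @export
permutation_group_test <- function(values, groups, n_perm = 10000, seed = NULL) {
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must be aligned.")
  }
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    abort("Need at least two groups.")
  }
  if (n_perm < 999) abort("Use at least 999 permutations.")
  if (!is.null(seed)) set.seed(seed)
  between_ss <- function(v, g) {
    grand <- mean(v)
    m <- tapply(v, g, mean)
    n_g <- tabulate(g)
    sum(n_g * (m - grand)^2)
  }
  obs <- between_ss(values, groups)
  perm <- vapply(
    seq_len(n_perm),
    function(i) between_ss(values, sample(groups)),
    numeric(1)
  )
  p <- (1 + sum(perm >= obs)) / (1 + n_perm)
  new_perm_test("label-shuffle between-group SS", obs, p, n_perm, seed)
}

#' Paired permutation test of round-2 versus round-1 accuracy
#'
#' Sign test on the within-rater differences `round2 - round1`: one-sided
#' for round 2 being more accurate.
#'
#' @param acc_round1,acc_round2 Aligned per-rater accuracy vectors.
#' @inheritParams permutation_sign_test
#' @return A `coop_perm_test` object.
#' @export
paired_round_test <- function(acc_round1, acc_round2, n_perm = 10000,
                              seed = NULL) {
  if (length(acc_round1) != length(acc_round2)) {
    abort("Round accuracy vectors must be aligned per rater.")
  }
  out <- permutation_sign_test(acc_round2 - acc_round1, n_perm, seed)
  out$method <- "paired sign-flip round2 - round1"
  out
}

# Per-rater log-likelihood curves on a parameter grid for a mixture guess
# rule P(Split) = par * comp1 + (1 - par) * comp0. Returns raters x grid.
rater_grid_loglik <- function(rater_id, g_split, comp1, comp0, grid) {
  p_mat <- outer(comp1, grid) + outer(comp0, 1 - grid)
  p_mat <- pmin(pmax(p_mat, 1e-12), 1 - 1e-12)
  ll <- log(p_mat)
  if (any(!g_split)) ll[!g_split, ] <- log1p(-p_mat[!g_split, , drop = FALSE])
  rowsum(ll, group = rater_id)
}

#' Recover generative parameters from simulated study tables
#'
#' Validates the whole pipeline by re-estimating its own parameters from the
#' emitted tables: gender cooperation-type probabilities and the tremble from
#' the match histories, and the strategy weights (`lambda_optimize`,
#' `heuristic_adherence`) by grid-search maximum likelihood on the guesses of
#' raters in the None and Label arms, where the likelihood has no latent
#' appearance cue. The tremble is the mismatch share between realized
#' round-2+ choices and the conditional-cooperation law applied to the known
#' types and realized histories; type probabilities are de-trembled round-1
#' Split shares. Intervals: Wilson score intervals on the underlying
#' proportions, mapped through the de-tremble inversion, for the cohort
#' parameters (a percentile bootstrap on proportions this small is known to
#' undercover); rater-resampling percentile bootstrap, widened by one grid
#' step against the discretisation of the grid MLE, for the strategy
#' parameters.
#'
#' @param players,matches,raters,guesses The pipeline tables.
#' @param true_values Optional named list of generating values; when given,
#'   each report row gains a coverage flag.
#' @param grid Grid for the strategy-parameter likelihood search (ties break
#'   toward the smaller value).
#' @param n_boot Bootstrap replicates.
#' @param seed Optional integer seed.
#' @return A tibble of class `coop_recovery`: `parameter`, `truth`,
#'   `estimate`, `lower`, `upper`, `covered`.
#' @export
recover_parameters <- function(players, matches, raters, guesses,
                               true_values = NULL,
                               grid = seq(0, 1, by = 0.01),
                               n_boot = 200, seed = NULL) {
  if (length(grid) < 2 || any(grid < 0) || any(grid > 1)) {
    abort("`grid` must have >= 2 values inside [0, 1].")
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- sort(grid)

  truths <- player_truths(matches) %>%
    left_join(select(players, "player_id", "gender", "ptype"), by = "player_id")

  # --- cohort parameters: per-match sufficient statistics ------------------
  long <- matches %>%
    tidyr::pivot_longer(
      c("choice_a", "choice_b"),
      names_to = "side", values_to = "choice"
    ) %>%
    mutate(
      player_id = ifelse(.data$side == "choice_a", .data$id_a, .data$id_b),
      partner_id = ifelse(.data$side == "choice_a", .data$id_b, .data$id_a)
    ) %>%
    select("match_id", "round", "player_id", "partner_id", "choice")
  # the partner's previous realized choice, taken from the partner's own row
  prev_tbl <- long %>%
    mutate(round = .data$round + 1L) %>%
    select("match_id", "round", partner_id = "player_id", partner_prev = "choice")
  law_dev <- long %>%
    left_join(select(players, "player_id", "ptype"), by = "player_id") %>%
    left_join(prev_tbl, by = c("match_id", "partner_id", "round")) %>%
    filter(.data$round >= 2L) %>%
    mutate(deviates = .data$choice != intended_choice(.data$ptype, .data$partner_prev))

  wilson_ci <- function(k, n) {
    z <- qnorm(0.975)
    phat <- k / n
    denom <- 1 + z^2 / n
    center <- (phat + z^2 / (2 * n)) / denom
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
    c(max(0, center - half), min(1, center + half))
  }
  n_dev <- nrow(law_dev)
  k_dev <- sum(law_dev$deviates)
  t_hat <- k_dev / n_dev
  ci_t <- wilson_ci(k_dev, n_dev)
  # invert q = p + t - 2pt, the realized-share map under the tremble;
  # interval bounds take the least favourable tremble inside its own interval
  detremble <- function(q, t) min(max((q - t) / (1 - 2 * t), 0), 1)
  cohort_row <- function(gender) {
    sub <- truths[truths$gender == gender, ]
    k <- sum(sub$own_r1 == "Split")
    ci_q <- wilson_ci(k, nrow(sub))
    tibble(
      parameter = paste0("p_coop_", gender),
      estimate = detremble(k / nrow(sub), t_hat),
      lower = min(detremble(ci_q[1], ci_t[1]), detremble(ci_q[1], ci_t[2])),
      upper = max(detremble(ci_q[2], ci_t[1]), detremble(ci_q[2], ci_t[2]))
    )
  }

  # --- strategy parameters: grid MLE on cue-free arms ----------------------
  cue_free <- raters$rater_id[raters$treatment %in% c("none", "label")]
  g1 <- guesses %>%
    filter(.data$round == 1L, .data$rater_id %in% cue_free) %>%
    left_join(select(raters, "rater_id", "treatment", "belief_male",
                     "belief_female"), by = "rater_id") %>%
    left_join(select(truths, "player_id", "gender"), by = "player_id") %>%
    mutate(post = posterior_split_pct(
      .data$belief_male, .data$belief_female, .data$treatment != "none",
      .data$gender, NA_character_, 0.5, 1
    ))
  ll_lambda <- rater_grid_loglik(
    g1$rater_id, g1$guess == "Split",
    comp1 = as.numeric(g1$post >= 50), comp0 = g1$post / 100, grid
  )
  mle_from <- function(ll_mat, idx = seq_len(nrow(ll_mat))) {
    grid[which.max(colSums(ll_mat[idx, , drop = FALSE]))]
  }
  est_lambda <- mle_from(ll_lambda)

  g2 <- guesses %>%
    filter(.data$round == 2L, .data$rater_id %in% cue_free) %>%
    left_join(select(raters, "rater_id", "treatment", "belief_male",
                     "belief_female"), by = "rater_id") %>%
    left_join(select(truths, "player_id", "gender", "own_r1", "partner_r1"),
              by = "player_id") %>%
    mutate(
      post = posterior_split_pct(
        .data$belief_male, .data$belief_female, .data$treatment != "none",
        .data$gender, NA_character_, 0.5, 1
      ),
      heur = heuristic_prediction(.data$own_r1, .data$partner_r1),
      fallback = est_lambda * as.numeric(.data$post >= 50) +
        (1 - est_lambda) * .data$post / 100
    )
  ll_adh <- rater_grid_loglik(
    g2$rater_id, g2$guess == "Split",
    comp1 = as.numeric(g2$heur == "Split"), comp0 = g2$fallback, grid
  )
  est_adh <- mle_from(ll_adh)

  nr <- nrow(ll_lambda)
  boot_idx <- matrix(sample.int(nr, n_boot * nr, replace = TRUE), nrow = n_boot)
  boot_lambda <- apply(boot_idx, 1, function(i) mle_from(ll_lambda, i))
  boot_adh <- apply(boot_idx, 1, function(i) mle_from(ll_adh, i))

  # percentile bootstrap over raters, widened by one grid step to absorb
  # the discretisation of the grid MLE
  step <- max(diff(grid))
  ci <- function(x) {
    q <- quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    c(max(0, q[1] - step), min(1, q[2] + step))
  }
  ci_lambda <- ci(boot_lambda)
  ci_adh <- ci(boot_adh)
  out <- bind_rows(
    cohort_row("male"),
    cohort_row("female"),
    tibble(parameter = "tremble", estimate = t_hat,
           lower = ci_t[1], upper = ci_t[2]),
    tibble(parameter = "lambda_optimize", estimate = est_lambda,
           lower = ci_lambda[1], upper = ci_lambda[2]),
    tibble(parameter = "heuristic_adherence", estimate = est_adh,
           lower = ci_adh[1], upper = ci_adh[2])
  ) %>%
    mutate(
      truth = purrr::map_dbl(
        .data$parameter,
        ~ (true_values[[.x]] %||% NA_real_)
      ),
      covered = !is.na(.data$truth) &
        .data$truth >= .data$lower & .data$truth <= .data$upper
    ) %>%
    select("parameter", "truth", "estimate", "lower", "upper", "covered")
  class(out) <- c("coop_recovery", class(out))
  out
}

#' Tidy a parameter-recovery report
#'
#' @param x A `coop_recovery` tibble.
#' @param ... Unused.
#' @return The underlying tibble (`tidy`) or a one-row coverage summary
#'   (`glance`).
#' @exportS3Method generics::tidy
tidy.coop_recovery <- function(x, ...) {
  as_tibble(unclass2(x))
}

#' @rdname tidy.coop_recovery
#' @exportS3Method generics::glance
glance.coop_recovery <- function(x, ...) {
  tibble(
    n_parameters = nrow(x),
    n_covered = sum(x$covered, na.rm = TRUE),
    max_abs_error = max(abs(x$estimate - x$truth), na.rm = TRUE)
  )
}

unclass2 <- function(x) {
  class(x) <- setdiff(class(x), "coop_recovery")
  x
}
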