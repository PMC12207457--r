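# Independent oracles and small builders shared across the suite.

constant_policy <- function(a) {
  force(a)
  function(round, others_avg, public_account) a
}

# Direct interpretive replay of a group of delegate programs, written
# independently of delegate_policy/play_game: plain loops over rounds,
# explicit account bookkeeping, and its own nearest-element rounding
# (lexicographic order on distance then negated value, so ties go up).
interpret_delegates <- function(tables, rounds = 10) {
  space <- tables[[1]]$action_space
  nearest_up <- function(avg) {
    ranking <- order(abs(space - avg), -space)
    space[ranking[1]]
  }
  n <- length(tables)
  acts <- matrix(NA_integer_, nrow = rounds, ncol = n)
  account <- 0
  for (r in seq_len(rounds)) {
    for (i in seq_len(n)) {
      tb <- tables[[i]]
      if (r == 1) {
        acts[r, i] <- tb$starting_action
      } else {
        avg <- sum(acts[r - 1, -i]) / (n - 1)
        key <- nearest_up(avg)
        strat <- if (account >= tb$switch_value) tb$strategy2 else tb$strategy1
        acts[r, i] <- strat[[which(space == key)]]
      }
    }
    account <- account + sum(acts[r, ])
  }
  acts
}

# Wrap a single played group as a minimal one-game study table.
one_group_study <- function(policies, config = crd_config(), seed = 1,
                            group_id = 1L, game = 1L) {
  traj <- play_game(policies, config, seed = seed)
  dplyr::mutate(
    tibble::as_tibble(traj),
    group_id = group_id, game = game,
    treatment_choices = length(config$action_space),
    treatment_delegation = FALSE,
    .before = 1
  )
}

# Textbook Welch statistic, Welch-Satterthwaite df and p-value.
welch_oracle <- function(a, b, alternative = "two.sided") {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(-abs(t), df),
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df)
  )
  list(statistic = t, df = df, p_value = p)
}

# Two-sided Fisher p by full enumeration of all 2x2 tables with the
# observed margins, summing hypergeometric probabilities no larger than
# the observed table's (with the standard relative tolerance).
fisher_oracle_two_sided <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Closed-form sums of squares for a balanced two-factor design with
# interaction (textbook decomposition).
anova_balanced_oracle <- function(y, a, b) {
  n <- length(y)
  gm <- mean(y)
  n_a <- table(a)[1]
  n_b <- table(b)[1]
  ss_a <- sum(tapply(y, a, function(v) length(v) * (mean(v) - gm)^2))
  ss_b <- sum(tapply(y, b, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(y, list(a, b), mean)
  cell_n <- table(a, b)
  ss_cells <- sum(cell_n * (cell_means - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((y - ave(y, a, b))^2)
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_res = ss_res)
}
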