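#' Play one collective-risk dilemma game
#'
#' Runs the round-by-round engine: in each round every player's policy is
#' called with the same pre-round information (moves within a round are
#' simultaneous), contributions are validated against the action space and
#' added to the public account, and after the last round the risky outcome is
#' resolved by [resolve_outcome()].
#'
#' A *policy* is a function `function(round, others_avg, public_account)`
#' returning an element of `config$action_space`:
#' * `round` — 1-based round index;
#' * `others_avg` — the mean contribution of the *other* group members in the
#'   previous round (a real number), or `NA` in round 1 when no history
#'   exists; policies must not rely on its value in round 1;
#' * `public_account` — the public account accumulated through the previous
#'   round (0 in round 1).
#'
#' @param policies A list of exactly `config$group_size` policy functions.
#' @param config A [crd_config()].
#' @param seed Optional integer seed for the risk draw (the only stochastic
#'   step); the contribution phase is fully deterministic.
#'
#' @return A `crd_trajectory`: a list with the contributions matrix
#'   (`rounds` x `group_size`), `public_account_by_round`,
#'   `final_public_account`, `success`, `loss_event` (`NA` when the group
#'   succeeded) and integer `payoffs`. Convert to the long per-round table
#'   with [as_tibble()][tibble::as_tibble].
#' @examples
#' fair <- function(round, others_avg, public_account) 2
#' g <- play_game(rep(list(fair), 4), crd_config(), seed = 1)
#' g$final_public_account  # 80: four fair-share players meet the target
#' g$payoffs               # each keeps 40 - 20 = 20 ECoins
#' @seealso [delegate_policy()], [profile_policy()]
#' @export
play_game <- function(policies, config = crd_config(), seed = NULL) {
  if (!is_crd_config(config)) abort("`config` must be a crd_config.")
  if (!is.list(policies) || length(policies) != config$group_size) {
    abort(sprintf(
      "`policies` must be a list of exactly %d functions (one per player).",
      config$group_size
    ))
  }
  if (!all(vapply(policies, is.function, logical(1)))) {
    abort("every element of `policies` must be a function.")
  }

  n <- config$group_size
  contributions <- matrix(NA_integer_, nrow = config$rounds, ncol = n)
  public <- 0L
  public_by_round <- integer(config$rounds)
  prev <- NULL # previous-round contributions

  for (r in seq_len(config$rounds)) {
    acts <- integer(n)
    for (i in seq_len(n)) {
      others_avg <- if (is.null(prev)) NA_real_ else mean(prev[-i])
      a <- policies[[i]](r, others_avg, public)
      if (length(a) != 1 || is.na(a) || !a %in% config$action_space) {
        abort(sprintf(
          "policy %d returned %s in round %d; actions must be one of {%s}.",
          i, deparse(a), r, paste(config$action_space, collapse = ",")
        ))
      }
      acts[i] <- as.integer(a)
    }
    contributions[r, ] <- acts
    public <- public + sum(acts)
    public_by_round[r] <- public
    prev <- acts
  }

  resolve_outcome(
    structure(
      list(
        config = config, contributions = contributions,
        public_account_by_round = public_by_round,
        final_public_account = public
      ),
      class = "crd_trajectory"
    ),
    seed = seed
  )
}

#' Resolve the risky outcome of a completed contributions table
#'
#' Success means the final public account reached the threshold (inclusive).
#' A failing group faces a single shared Bernoulli(`risk`) draw: on a loss
#' event every member's payoff is 0, otherwise each keeps their remaining
#' endowment (endowment minus own total contribution), exactly as successful
#' groups do.
#'
#' @param trajectory A `crd_trajectory` whose contributions are complete
#'   (payoffs may be unset).
#' @param seed Optional integer seed making the loss draw reproducible.
#' @return The trajectory with `success`, `loss_event` and `payoffs` filled.
#' @export
resolve_outcome <- function(trajectory, seed = NULL) {
  stopifnot(inherits(trajectory, "crd_trajectory"))
  cfg <- trajectory$config
  total <- sum(trajectory$contributions)
  stopifnot(total == trajectory$final_public_account)
  success <- total >= cfg$threshold
  loss_event <- if (success) NA else with_seed_(seed, runif(1) < cfg$risk)
  remaining <- cfg$endowment - colSums(trajectory$contributions)
  payoffs <- if (!success && loss_event) rep(0L, cfg$group_size) else as.integer(remaining)
  trajectory$success <- success
  trajectory$loss_event <- loss_event
  trajectory$payoffs <- payoffs
  trajectory
}

#' @export
print.crd_trajectory <- function(x, ...) {
  cat(
    "<crd_trajectory> public account ", x$final_public_account, "/",
    x$config$threshold, " (", if (x$success) "success" else "failure", ")",
    if (!x$success) paste0(", loss event: ", x$loss_event), "\n",
    sep = ""
  )
  cat("payoffs:", x$payoffs, "\n")
  invisible(x)
}

#' Long-format view of a trajectory
#'
#' One row per (round, player): the canonical serialization used throughout
#' the analysis layer.
#'
#' @param x A `crd_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns round, player_id, contribution,
#'   public_account_after_round, success, loss_event, payoff.
#' @export
as_tibble.crd_trajectory <- function(x, ...) {
  cfg <- x$config
  tibble(
    round = rep(seq_len(cfg$rounds), each = cfg$group_size),
    player_id = rep(seq_len(cfg$group_size), times = cfg$rounds),
    contribution = as.integer(t(x$contributions)),
    public_account_after_round =
      rep(x$public_account_by_round, each = cfg$group_size),
    success = x$success,
    loss_event = if (is.na(x$loss_event)) NA else x$loss_event,
    payoff = rep(x$payoffs, times = cfg$rounds)
  )
}
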