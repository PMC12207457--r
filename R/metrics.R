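#' Frequency of nonzero contributions
#'
#' The fraction of rounds in which a player contributed a strictly positive
#' amount; a participant who always contributes something scores 10/10 = 1.
#'
#' @param actions Integer vector of one player's per-round contributions.
#' @param rounds Expected length of `actions`.
#' @return A real number in `[0, 1]`.
#' @examples
#' contribution_frequency(rep(2, 10)) # 1
#' contribution_frequency(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)) # 0.5
#' @export
contribution_frequency <- function(actions, rounds = 10) {
  if (length(actions) != rounds || anyNA(actions)) {
    abort(sprintf("`actions` must be a complete vector of %d contributions.", rounds))
  }
  mean(actions > 0)
}

#' Per-group summary metrics
#'
#' One row per (group, game): the final public account, whether the group
#' reached the threshold, and the variance of the members' final *private
#' accounts* — the within-group inequality measure. Private accounts are
#' taken pre-risk (endowment minus own total contribution) so the measure
#' reflects contribution asymmetry rather than the shared group-level
#' gamble; set `post_risk = TRUE` to use realized payoffs instead.
#'
#' @param study A long study table from [generate_study()] or [read_study()].
#' @param endowment Initial per-player endowment in ECoins.
#' @param post_risk Use realized payoffs instead of pre-risk private accounts.
#' @return A tibble keyed by (group_id, game) with treatment labels,
#'   final_public_account, success and private_account_variance (sample
#'   variance, n - 1 denominator).
#' @export
group_metrics <- function(study, endowment = 40, post_risk = FALSE) {
  per_player <- study |>
    dplyr::group_by(
      .data$group_id, .data$game, .data$player_id,
      .data$treatment_choices, .data$treatment_delegation
    ) |>
    dplyr::summarise(
      total = sum(.data$contribution),
      final_public_account = max(.data$public_account_after_round),
      success = .data$success[1],
      payoff = .data$payoff[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      private_account = if (post_risk) .data$payoff else endowment - .data$total
    )
  per_player |>
    dplyr::group_by(
      .data$group_id, .data$game,
      .data$treatment_choices, .data$treatment_delegation
    ) |>
    dplyr::summarise(
      final_public_account = .data$final_public_account[1],
      success = .data$success[1],
      private_account_variance = stats::var(.data$private_account),
      .groups = "drop"
    )
}

#' Per-individual summary metrics
#'
#' One row per (player, game): total contribution and contribution
#' frequency, carrying the treatment labels.
#'
#' @inheritParams group_metrics
#' @return A tibble keyed by (player_id, game).
#' @export
individual_metrics <- function(study) {
  study |>
    dplyr::group_by(
      .data$player_id, .data$game, .data$group_id,
      .data$treatment_choices, .data$treatment_delegation
    ) |>
    dplyr::summarise(
      total_contribution = sum(.data$contribution),
      contribution_frequency = mean(.data$contribution > 0),
      success = .data$success[1],
      .groups = "drop"
    )
}

#' Between-game change in an individual's total contribution
#'
#' Game 2 total minus Game 1 total; positive values mean the individual
#' increased their contributions after the surprise restart.
#'
#' @param game1_actions,game2_actions Equal-length per-round contribution
#'   vectors for the same individual.
#' @return An integer delta in ECoins.
#' @export
between_game_delta <- function(game1_actions, game2_actions) {
  if (length(game1_actions) != length(game2_actions)) {
    abort("the two action vectors must have the same length.")
  }
  as.integer(sum(game2_actions) - sum(game1_actions))
}

#' Probability of changing behavioral cluster between games
#'
#' The fraction of individuals whose assigned behavior label differs
#' between Game 1 and Game 2.
#'
#' @param labels_game1,labels_game2 Parallel label vectors (one entry per
#'   individual, same order).
#' @return A real number in `[0, 1]`.
#' @export
cluster_change_rate <- function(labels_game1, labels_game2) {
  if (length(labels_game1) != length(labels_game2)) {
    abort("label vectors must have the same length.")
  }
  mean(as.character(labels_game1) != as.character(labels_game2))
}

#' Per-individual between-game deltas for a whole study
#'
#' Convenience wrapper computing [between_game_delta()] for every individual
#' present in both games, tagged with their Game 1 group outcome (the
#' conditioning variable for revision analyses).
#'
#' @inheritParams group_metrics
#' @return A tibble with player_id, treatment labels, game1_success and
#'   delta.
#' @export
study_deltas <- function(study) {
  ind <- individual_metrics(study)
  g1 <- dplyr::filter(ind, .data$game == 1)
  g2 <- dplyr::filter(ind, .data$game == 2)
  dplyr::inner_join(
    dplyr::select(g1, "player_id", "group_id", "treatment_choices",
                  "treatment_delegation", game1_success = "success",
                  g1_total = "total_contribution"),
    dplyr::select(g2, "player_id", g2_total = "total_contribution"),
    by = "player_id"
  ) |>
    dplyr::mutate(delta = .data$g2_total - .data$g1_total)
}
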