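#' Behavioral contribution profiles
#'
#' The four contributor classes observed in collective-risk dilemmas: *fair*
#' players contribute the per-round fair share (2 ECoins) throughout; *high*
#' and *low* players sit above and below it all game; *early* players front-
#' load (above 2 in rounds 1-5, below 2 in rounds 6-10). A profile is a
#' latent per-round target sequence plus Gaussian jitter; realized actions
#' are the targets plus noise snapped onto the treatment's action space.
#'
#' Default targets: fair 2; high 3.4 (snaps to 4 under 3 choices, 3 under
#' 5); low 0.8 (snaps to 0 under 3 choices but 1 under 5 — low contributors
#' can be selfish without contributing zero only when the action space is
#' fine enough); early 4 in rounds 1-5 and 0 afterwards.
#'
#' @param label One of `"early"`, `"high"`, `"fair"`, `"low"`.
#' @param targets Optional length-`rounds` numeric vector of latent per-round
#'   contribution targets; defaults depend on `label`.
#' @param noise_sd Standard deviation of the per-round Gaussian jitter on the
#'   latent target (ECoins), default 0.25.
#' @param rounds Number of rounds the profile spans.
#' @return An object of class `behavior_profile`.
#' @export
behavior_profile <- function(label = c("early", "high", "fair", "low"),
                             targets = NULL, noise_sd = 0.25, rounds = 10) {
  label <- match.arg(label)
  if (is.null(targets)) {
    half1 <- ceiling(rounds / 2)
    targets <- switch(label,
      fair = rep(2, rounds),
      high = rep(3.4, rounds),
      low = rep(0.8, rounds),
      early = c(rep(4, half1), rep(0, rounds - half1))
    )
  }
  stopifnot(length(targets) == rounds, all(targets >= 0), noise_sd >= 0)
  structure(
    list(label = label, targets = as.numeric(targets), noise_sd = noise_sd),
    class = "behavior_profile"
  )
}

clip_ <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round policy realizing a behavioral profile
#'
#' Draws one Gaussian deviation per round up front (so the policy is a
#' deterministic function afterwards) and plays
#' `round_to_space(target + noise, space)` each round, with the latent value
#' clipped into `[0, max(space)]`. With `noise_sd = 0` the policy is fully
#' deterministic.
#'
#' @param profile A [behavior_profile()].
#' @param space The treatment's action space.
#' @param seed Integer seed for the noise draws.
#' @return A policy function for [play_game()].
#' @export
profile_policy <- function(profile, space = c(0, 2, 4), seed = NULL) {
  stopifnot(inherits(profile, "behavior_profile"))
  noise <- with_seed_(seed, rnorm(length(profile$targets), 0, profile$noise_sd))
  latent <- clip_(profile$targets + noise, 0, max(space))
  function(round, others_avg, public_account) {
    round_to_space(latent[round], space)
  }
}

#' Sample a delegate strategy table consistent with a profile
#'
#' Builds a program whose replayed behavior against fair-share opponents
#' tracks the profile's targets: the reaction-table entry for a rounded
#' others' average `x` is `round_to_space(base + w * (x - 2))`, where `base`
#' is the mean target for the phase the table governs (strategy 1: rounds
#' 1-5, strategy 2: rounds 6-10) and `w` is a reciprocity slope. With
#' probability `p_conditional` the table is genuinely conditional
#' (`w` drawn from {0.5, 1}); otherwise `w = 0`, strategy 2 copies
#' strategy 1 and the starting action equals the common entry, producing a
#' truly fixed-behavior program.
#'
#' Front-loaded (early-shaped) target sequences get a switch value drawn
#' from 41-50, which against fair opponents fires at the round-6 boundary
#' and implements the early-to-low drop through strategy 2; flat profiles
#' get a switch in 81-120 that is mostly immaterial before the target is
#' reached.
#'
#' @inheritParams profile_policy
#' @param p_conditional Probability that the sampled table is conditional.
#' @return A [strategy_table()]; the latent generating parameters (targets
#'   and slopes) are kept in the `"gen"` attribute so between-game revision
#'   can shift the latent targets and rebuild the same program structure.
#' @export
sample_strategy_table <- function(profile, space = c(0, 2, 4), seed = NULL,
                                  p_conditional = 0.9) {
  stopifnot(inherits(profile, "behavior_profile"))
  with_seed_(seed, {
    conditional <- runif(1) < p_conditional
    n <- length(profile$targets)
    half1 <- ceiling(n / 2)
    base1 <- mean(profile$targets[seq_len(half1)])
    base2 <- mean(profile$targets[(half1 + 1):n])
    front_loaded <- (base1 - base2) > 1
    w1 <- if (conditional) sample(c(0.5, 1), 1) else 0
    w2 <- if (conditional) sample(c(0.5, 1), 1) else 0
    switch_value <- if (front_loaded) sample(41:50, 1) else sample(81:120, 1)
    if (!conditional && !front_loaded) base2 <- base1 # truly fixed program
    build_generated_table(profile$targets, base1, base2, w1, w2,
      switch_value, space,
      start_latent = profile$targets[1]
    )
  })
}

# Deterministic table construction from latent generating parameters.
build_generated_table <- function(targets, base1, base2, w1, w2, switch_value,
                                  space, start_latent) {
  mx <- max(space)
  entries <- function(base, w) {
    vapply(space, function(x) {
      round_to_space(clip_(base + w * (x - 2), 0, mx), space)
    }, numeric(1))
  }
  tb <- strategy_table(
    starting_action = round_to_space(clip_(start_latent, 0, mx), space),
    strategy1 = entries(base1, w1),
    switch_value = switch_value,
    strategy2 = entries(base2, w2),
    action_space = space
  )
  attr(tb, "gen") <- list(
    targets = targets, base1 = base1, base2 = base2, w1 = w1, w2 = w2,
    switch_value = switch_value, start_latent = start_latent
  )
  tb
}

#' Revision parameters applied between Game 1 and Game 2
#'
#' The experimental findings this generator emulates fix only the *signs*
#' of between-game adjustment; the magnitudes are free generator
#' parameters. `delta_up` is
#' the upward latent-target shift (ECoins per round) applied by delegating
#' members of failed groups; `delta_down` the downward correction applied by
#' delegating members of successful groups that overshot the target;
#' `p_giveup` the probability that a non-delegating member of a failed group
#' abandons the public good and becomes a low contributor.
#'
#' @param delta_up,delta_down Non-negative latent shifts in ECoins/round.
#' @param p_giveup Probability in `[0, 1]`.
#' @return A list of class `revision_params`.
#' @export
revision_params <- function(delta_up = 1, delta_down = 0.5, p_giveup = 0.6) {
  stopifnot(delta_up >= 0, delta_down >= 0, p_giveup >= 0, p_giveup <= 1)
  structure(list(delta_up = delta_up, delta_down = delta_down,
                 p_giveup = p_giveup), class = "revision_params")
}

#' Construct one synthetic study member
#'
#' Bundles a behavioral profile with its realization machinery: in
#' delegation treatments a sampled [strategy_table()], otherwise the latent
#' targets a [profile_policy()] will jitter at play time.
#'
#' @inheritParams sample_strategy_table
#' @param delegation Logical: does this member program a delegate?
#' @return A list of class `crd_member`.
#' @export
make_member <- function(profile, delegation, space = c(0, 2, 4), seed = NULL,
                        p_conditional = 0.9) {
  stopifnot(inherits(profile, "behavior_profile"))
  table <- if (delegation) {
    sample_strategy_table(profile, space, seed = seed,
                          p_conditional = p_conditional)
  }
  structure(
    list(profile = profile, delegation = delegation, space = space,
         table = table),
    class = "crd_member"
  )
}

member_policy <- function(member, config, noise_seed = NULL) {
  if (member$delegation) {
    delegate_policy(member$table, config)
  } else {
    profile_policy(member$profile, config$action_space, seed = noise_seed)
  }
}

#' Revise a member's behavior after Game 1
#'
#' Outcome-dependent adjustment between the two games. Delegating members of
#' failed groups shift their latent targets up by `params$delta_up` and
#' reprogram their delegate with the same conditional structure; delegating
#' members of successful groups that overshot the target shift down by
#' `params$delta_down`. Non-delegating members of failed groups give up on
#' the public good with probability `params$p_giveup`, adopting the low-
#' contributor profile; successful non-delegating members are unchanged.
#' With all parameters zero the member is returned untouched.
#'
#' @param member A [make_member()] record with its Game 1 context.
#' @param group_success Logical: did the member's group reach the threshold
#'   in Game 1?
#' @param overshoot ECoins by which the final public account exceeded the
#'   threshold (0 for failed groups).
#' @param params A [revision_params()].
#' @param seed Integer seed for the give-up draw.
#' @return The (possibly) revised `crd_member`.
#' @export
revise_behavior <- function(member, group_success, overshoot = 0,
                            params = revision_params(), seed = NULL) {
  stopifnot(inherits(member, "crd_member"))
  mx <- max(member$space)
  if (member$delegation) {
    shift <-
      if (!group_success) params$delta_up
      else if (overshoot > 0) -params$delta_down
      else 0
    if (shift == 0) {
      return(member)
    }
    gen <- attr(member$table, "gen")
    member$profile$targets <- clip_(member$profile$targets + shift, 0, mx)
    member$table <- build_generated_table(
      targets = member$profile$targets,
      base1 = clip_(gen$base1 + shift, 0, mx),
      base2 = clip_(gen$base2 + shift, 0, mx),
      w1 = gen$w1, w2 = gen$w2, switch_value = gen$switch_value,
      space = member$space, start_latent = clip_(gen$start_latent + shift, 0, mx)
    )
    member
  } else {
    if (group_success || params$p_giveup == 0) {
      return(member)
    }
    gives_up <- with_seed_(seed, runif(1) < params$p_giveup)
    if (gives_up) {
      member$profile <- behavior_profile(
        "low", noise_sd = member$profile$noise_sd,
        rounds = length(member$profile$targets)
      )
      # under 3 choices the low target snaps to 0: a literal give-up
      member$profile$targets <- rep(0, length(member$profile$targets))
    }
    member
  }
}

#' Default behavioral-profile mixtures per treatment cell
#'
#' The fair-contributor shares are anchored on the observed treatment-level
#' fractions (3 choices: 46% delegation / 57% no-delegation; 5 choices: 47%
#' delegation / 40% no-delegation). The remaining mass follows the observed
#' qualitative ordering: delegation cells hold more high and low
#' contributors and few early contributors, no-delegation cells many early
#' contributors and almost no high contributors, and fewer low contributors
#' under 5 choices than under 3.
#'
#' @return A tibble with columns choices, delegation, early, high, fair, low
#'   (rows sum to 1).
#' @export
default_mixtures <- function() {
  tibble(
    choices = c(3L, 3L, 5L, 5L),
    delegation = c(TRUE, FALSE, TRUE, FALSE),
    early = c(0.07, 0.30, 0.06, 0.45),
    high = c(0.27, 0.02, 0.27, 0.05),
    fair = c(0.46, 0.55, 0.47, 0.40),
    low = c(0.20, 0.13, 0.20, 0.10)
  )
}

#' Describe a 2x2 synthetic study
#'
#' The factorial design of the study: number of choices (3 vs 5) crossed
#' with delegation (programmed agents vs direct play), `n_groups` groups of
#' four per cell, each playing two consecutive 10-round games with
#' outcome-dependent revision in between.
#'
#' @param n_groups Groups per treatment cell.
#' @param mixtures Profile mixture per cell, as [default_mixtures()].
#' @param noise_sd Per-round latent jitter for direct play (ECoins).
#' @param p_conditional Probability a sampled delegate table is conditional.
#' @param revision A [revision_params()].
#' @param seed Master seed; every random stream in [generate_study()] is
#'   derived from it.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_groups = 30, mixtures = default_mixtures(),
                         noise_sd = 0.25, p_conditional = 0.9,
                         revision = revision_params(), seed = 1) {
  stopifnot(n_groups >= 1)
  probs <- as.matrix(mixtures[, c("early", "high", "fair", "low")])
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-8)) {
    abort("each mixture row must be a probability vector summing to 1.")
  }
  structure(
    list(n_groups = as.integer(n_groups), mixtures = mixtures,
         noise_sd = noise_sd, p_conditional = p_conditional,
         revision = revision, seed = as.integer(seed)),
    class = "study_design"
  )
}

#' Generate a full synthetic study dataset
#'
#' For every treatment cell and group: sample four member profiles from the
#' cell's mixture; build delegate tables (delegation cells) or jittered
#' profile policies (no-delegation cells); play Game 1; apply
#' [revise_behavior()] to each member given the group outcome; play Game 2
#' with the same group. The result is the long per-round table the analysis
#' layer consumes, with one row per (group, game, round, player).
#'
#' @param design A [study_design()].
#' @return A tibble of class `crd_study` with columns group_id, game, round,
#'   player_id, treatment_choices, treatment_delegation, contribution,
#'   public_account_after_round, success, loss_event, payoff. Companion
#'   tables are attached as attributes and retrieved with [study_tables()]
#'   (delegate programs, per game) and [study_profiles()] (generating
#'   profile labels, per game).
#' @examples
#' study <- generate_study(study_design(n_groups = 2, seed = 42))
#' dplyr::count(study, treatment_choices, treatment_delegation)
#' @export
generate_study <- function(design) {
  stopifnot(inherits(design, "study_design"))
  cells <- design$mixtures
  n_cells <- nrow(cells)
  group_seeds <- matrix(
    split_seeds(design$seed, n_cells * design$n_groups),
    nrow = n_cells
  )
  labels <- c("early", "high", "fair", "low")

  rows <- list()
  table_rows <- list()
  profile_rows <- list()
  group_id <- 0L

  for (ci in seq_len(n_cells)) {
    cell <- cells[ci, ]
    config <- crd_config_choices(cell$choices)
    probs <- as.numeric(cell[, labels])
    for (gi in seq_len(design$n_groups)) {
      group_id <- group_id + 1L
      # independent substreams: profile draw, 4 member creations, 4 game-1
      # noise draws, 4 revisions, 4 game-2 noise draws, 2 risk draws
      sub <- split_seeds(group_seeds[ci, gi], 19)
      member_labels <- with_seed_(
        sub[1], sample(labels, config$group_size, replace = TRUE, prob = probs)
      )
      members <- lapply(seq_len(config$group_size), function(i) {
        make_member(
          behavior_profile(member_labels[i], noise_sd = design$noise_sd,
                           rounds = config$rounds),
          delegation = cell$delegation, space = config$action_space,
          seed = sub[1 + i], p_conditional = design$p_conditional
        )
      })

      for (game in 1:2) {
        noise_off <- if (game == 1) 5 else 13
        policies <- lapply(seq_along(members), function(i) {
          member_policy(members[[i]], config, noise_seed = sub[noise_off + i])
        })
        traj <- play_game(policies, config, seed = sub[17 + game])
        ids <- (group_id - 1L) * config$group_size + seq_len(config$group_size)
        rows[[length(rows) + 1L]] <- dplyr::mutate(
          as_tibble(traj),
          group_id = group_id, game = game,
          player_id = ids[.data$player_id],
          treatment_choices = cell$choices,
          treatment_delegation = cell$delegation,
          .before = 1
        )
        profile_rows[[length(profile_rows) + 1L]] <- tibble(
          player_id = ids, game = game,
          label = vapply(members, function(m) m$profile$label, character(1))
        )
        if (cell$delegation) {
          table_rows[[length(table_rows) + 1L]] <- dplyr::mutate(
            tables_to_tibble(lapply(members, `[[`, "table")),
            player_id = ids, game = game, .before = 1
          )
        }
        if (game == 1) {
          overshoot <- max(0, traj$final_public_account - config$threshold)
          members <- lapply(seq_along(members), function(i) {
            revise_behavior(members[[i]], traj$success, overshoot,
                            params = design$revision, seed = sub[9 + i])
          })
        }
      }
    }
  }

  out <- dplyr::relocate(
    dplyr::bind_rows(rows),
    "group_id", "game", "round", "player_id",
    "treatment_choices", "treatment_delegation"
  )
  structure(
    out,
    tables = if (length(table_rows)) dplyr::bind_rows(table_rows),
    profiles = dplyr::bind_rows(profile_rows),
    class = c("crd_study", class(out))
  )
}

#' @rdname generate_study
#' @param study A `crd_study` tibble.
#' @export
study_tables <- function(study) attr(study, "tables")

#' @rdname generate_study
#' @export
study_profiles <- function(study) attr(study, "profiles")
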