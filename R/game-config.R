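#' Collective-risk dilemma game configuration
#'
#' Bundles every parameter of the threshold public-goods game: the group must
#' accumulate `threshold` ECoins in the public account within `rounds` rounds
#' or each member loses their remaining endowment with probability `risk`.
#' Defaults are the study conditions: groups of 4 play 10 rounds with a 40
#' ECoin endowment, an 80 ECoin target and 50% risk, choosing each round from
#' either 3 actions (`c(0, 2, 4)`) or 5 actions (`c(0, 1, 2, 3, 4)`).
#'
#' @param group_size Number of players (>= 2).
#' @param rounds Number of contribution rounds (>= 1).
#' @param endowment Initial private endowment per player, in ECoins.
#' @param threshold Collective contribution target, in ECoins. Reaching it
#'   exactly counts as success.
#' @param risk Probability in `[0, 1]` that a failing group loses its
#'   remaining endowments (one draw per group, shared by all members).
#' @param action_space Strictly increasing integer vector of allowed per-round
#'   contributions; must contain 0, and its maximum times `rounds` may not
#'   exceed `endowment` (a player can never overdraw).
#'
#' @return An object of class `crd_config` (a validated list).
#' @examples
#' crd_config()                              # 3-choice default
#' crd_config(action_space = c(0, 1, 2, 3, 4))  # 5-choice variant
#' @export
crd_config <- function(group_size = 4, rounds = 10, endowment = 40,
                       threshold = 80, risk = 0.5,
                       action_space = c(0, 2, 4)) {
  stopifnot(
    length(group_size) == 1, group_size >= 2, group_size == as.integer(group_size),
    length(rounds) == 1, rounds >= 1, rounds == as.integer(rounds),
    length(endowment) == 1, endowment >= 0,
    length(threshold) == 1, threshold >= 0,
    length(risk) == 1, risk >= 0, risk <= 1
  )
  action_space <- as.integer(action_space)
  if (length(action_space) < 2 || any(diff(action_space) <= 0)) {
    abort("`action_space` must be strictly increasing with at least 2 actions.")
  }
  if (!0L %in% action_space) {
    abort("`action_space` must contain 0.")
  }
  if (max(action_space) * rounds > endowment) {
    abort("max(action_space) * rounds must not exceed the endowment.")
  }
  structure(
    list(
      group_size = as.integer(group_size), rounds = as.integer(rounds),
      endowment = as.integer(endowment), threshold = as.integer(threshold),
      risk = as.numeric(risk), action_space = action_space
    ),
    class = "crd_config"
  )
}

#' @export
print.crd_config <- function(x, ...) {
  cat(
    "<crd_config> ", x$group_size, " players, ", x$rounds, " rounds, ",
    "endowment ", x$endowment, ", threshold ", x$threshold, ", risk ", x$risk,
    ", actions {", paste(x$action_space, collapse = ","), "}\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname crd_config
#' @param choices Either `3` or `5`; shorthand for the two study action spaces.
#' @export
crd_config_choices <- function(choices) {
  if (!choices %in% c(3, 5)) abort("`choices` must be 3 or 5.")
  if (choices == 3) crd_config() else crd_config(action_space = 0:4)
}

is_crd_config <- function(x) inherits(x, "crd_config")
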