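#' Snap a real-valued average onto an action space
#'
#' Delegates react to the *rounded* average of the other members' previous
#' contributions: the average is mapped to the closest element of the action
#' space. Ties are broken toward the larger element, which only matters in
#' the 3-choice space `{0, 2, 4}` at averages 1.0 and 3.0; `tie_rule =
#' "down"` flips the rule for sensitivity checks against deposited data.
#'
#' @param average Non-negative real number, at most `max(space)`.
#' @param space Strictly increasing integer action space.
#' @param tie_rule `"up"` (default) or `"down"`: which element wins an exact
#'   tie between two neighbours.
#' @return The element of `space` closest to `average`.
#' @examples
#' round_to_space(2.7, 0:4) # 3
#' round_to_space(1, c(0, 2, 4)) # 2 (tie resolved upward)
#' @export
round_to_space <- function(average, space, tie_rule = c("up", "down")) {
  tie_rule <- match.arg(tie_rule)
  space <- as.integer(space)
  if (length(average) != 1 || is.na(average) || average < 0 || average > max(space)) {
    abort(sprintf("`average` must be a single value in [0, %d].", max(space)))
  }
  d <- abs(space - average)
  idx <- which(d == min(d))
  space[if (tie_rule == "up") max(idx) else min(idx)]
}

#' Create a delegate strategy table
#'
#' The full program a participant gives their artificial delegate: the action
#' played in round 1 (`starting_action`); `strategy1`, a complete reaction
#' table mapping each possible rounded average of the others' previous-round
#' contributions to an action; a public-account `switch_value`; and
#' `strategy2`, a second reaction table the agent permanently switches to
#' once the public account reaches `switch_value`.
#'
#' @param starting_action Element of `action_space` played in round 1.
#' @param strategy1,strategy2 Integer vectors of length
#'   `length(action_space)`: the action to play when the rounded others'
#'   average equals the corresponding element of `action_space`. All entries
#'   must lie in `action_space`.
#' @param switch_value Integer in `[0, 120]`. Once the public account at a
#'   round boundary is `>= switch_value`, the agent follows `strategy2` for
#'   the rest of the game (the switch never reverts).
#' @param action_space The treatment's action space.
#' @return An object of class `strategy_table`.
#' @examples
#' # an unconditional fair-share program
#' strategy_table(2, c(2, 2, 2), 80, c(2, 2, 2))
#' @export
strategy_table <- function(starting_action, strategy1, switch_value, strategy2,
                           action_space = c(0, 2, 4)) {
  action_space <- as.integer(action_space)
  strategy1 <- as.integer(strategy1)
  strategy2 <- as.integer(strategy2)
  k <- length(action_space)
  if (length(strategy1) != k || length(strategy2) != k) {
    abort("each strategy must define exactly one action per element of `action_space`.")
  }
  if (!starting_action %in% action_space ||
      !all(strategy1 %in% action_space) || !all(strategy2 %in% action_space)) {
    abort("starting action and all strategy entries must belong to `action_space`.")
  }
  if (length(switch_value) != 1 || switch_value < 0 || switch_value > 120) {
    abort("`switch_value` must lie in [0, 120].")
  }
  structure(
    list(
      action_space = action_space,
      starting_action = as.integer(starting_action),
      strategy1 = stats::setNames(strategy1, action_space),
      switch_value = as.integer(switch_value),
      strategy2 = stats::setNames(strategy2, action_space)
    ),
    class = "strategy_table"
  )
}

#' @export
print.strategy_table <- function(x, ...) {
  cat("<strategy_table> actions {", paste(x$action_space, collapse = ","),
    "}, start ", x$starting_action, ", switch at ", x$switch_value, "\n",
    sep = ""
  )
  cat("  strategy1:", paste(names(x$strategy1), x$strategy1, sep = "→", collapse = " "), "\n")
  cat("  strategy2:", paste(names(x$strategy2), x$strategy2, sep = "→", collapse = " "), "\n")
  invisible(x)
}

#' Turn a strategy table into a round policy
#'
#' Implements the delegate semantics: round 1 plays the starting action
#' unconditionally; from round 2 on, the agent evaluates the active reaction
#' table at the rounded others' previous-round average. The active table is
#' `strategy2` as soon as the public account at a round boundary has reached
#' the switch value (because the public account never decreases, the switch
#' is automatically irreversible), `strategy1` before that.
#'
#' @param table A [strategy_table()].
#' @param config A [crd_config()] with a matching action space.
#' @param tie_rule Passed to [round_to_space()].
#' @return A policy function usable with [play_game()].
#' @export
delegate_policy <- function(table, config = crd_config(),
                            tie_rule = c("up", "down")) {
  stopifnot(inherits(table, "strategy_table"))
  tie_rule <- match.arg(tie_rule)
  if (!identical(table$action_space, config$action_space)) {
    abort("the table's action space must equal the config's action space.")
  }
  function(round, others_avg, public_account) {
    if (round == 1) {
      return(table$starting_action)
    }
    strat <- if (public_account >= table$switch_value) table$strategy2 else table$strategy1
    key <- round_to_space(others_avg, table$action_space, tie_rule)
    unname(strat[[as.character(key)]])
  }
}

#' Classify how conditional a delegate program is
#'
#' Most participants program genuinely conditional delegates; a minority pick
#' the same action for every contingency. `strategy1_constant` flags tables
#' whose first reaction table is a single repeated action; `fully_constant`
#' additionally requires strategy 2 and the starting action to equal that
#' same action, so the agent's realized behavior is literally fixed no matter
#' what the group does.
#'
#' @param table A [strategy_table()].
#' @return A one-row tibble with logical columns `strategy1_constant` and
#'   `fully_constant`.
#' @export
classify_table <- function(table) {
  stopifnot(inherits(table, "strategy_table"))
  s1_const <- length(unique(table$strategy1)) == 1
  fully <- s1_const &&
    length(unique(table$strategy2)) == 1 &&
    table$strategy2[[1]] == table$strategy1[[1]] &&
    table$starting_action == table$strategy1[[1]]
  tibble(strategy1_constant = s1_const, fully_constant = fully)
}

#' Serialize strategy tables to a flat row set
#'
#' One row per table: start, the strategy-1 entry for each rounded average,
#' the switch value, then the strategy-2 entries (columns `s1_at_<a>`,
#' `s2_at_<a>`).
#'
#' @param tables A list of [strategy_table()] objects (or one table).
#' @return A tibble with one row per table.
#' @export
tables_to_tibble <- function(tables) {
  if (inherits(tables, "strategy_table")) tables <- list(tables)
  purrr::map_dfr(tables, function(tb) {
    row <- c(
      start = tb$starting_action,
      stats::setNames(unname(tb$strategy1), paste0("s1_at_", tb$action_space)),
      switch = tb$switch_value,
      stats::setNames(unname(tb$strategy2), paste0("s2_at_", tb$action_space))
    )
    as_tibble(as.list(row))
  })
}
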