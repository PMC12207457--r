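space3 <- c(0, 2, 4)
space5 <- 0:4

test_that("round_to_space snaps to the nearest action, ties upward", {
  expect_equal(round_to_space(2.0, space5), 2)
  expect_equal(round_to_space(2.7, space5), 3)
  expect_equal(round_to_space(1.0, space3), 2) # equidistant: up
  expect_equal(round_to_space(1.0, space3, tie_rule = "down"), 0)
  expect_equal(round_to_space(3.0, space3), 4)
  expect_equal(round_to_space(0, space3), 0)
  expect_equal(round_to_space(4, space5), 4)
  # idempotent on the space itself
  for (a in space5) expect_equal(round_to_space(a, space5), a)
  expect_error(round_to_space(-0.1, space3), "in \\[0, 4\\]")
  expect_error(round_to_space(4.5, space3), "in \\[0, 4\\]")
})

test_that("strategy tables are validated", {
  expect_error(strategy_table(2, c(2, 2), 80, c(0, 0, 0)), "exactly one action")
  expect_error(strategy_table(3, c(2, 2, 2), 80, c(0, 0, 0)), "belong")
  expect_error(strategy_table(2, c(2, 2, 2), 121, c(0, 0, 0)), "\\[0, 120\\]")
  expect_error(
    delegate_policy(strategy_table(2, c(2, 2, 2), 80, c(0, 0, 0)),
                    crd_config(action_space = 0:4)),
    "action space"
  )
})

test_that("the switch fires on the pre-round public account and is sticky", {
  # four identical agents: start 2, strategy1 constant 2, switch 80,
  # strategy2 constant 0. The pre-round account peaks at 72 < 80, so the
  # switch never fires and the group lands exactly on the threshold.
  tb <- strategy_table(2, c(2, 2, 2), 80, c(0, 0, 0))
  g <- play_game(rep(list(delegate_policy(tb)), 4), crd_config(), seed = 1)
  expect_true(all(g$contributions == 2))
  expect_equal(g$final_public_account, 80)

  # switch at 72 fires exactly at the round-10 boundary
  tb72 <- strategy_table(2, c(2, 2, 2), 72, c(0, 0, 0))
  g72 <- play_game(rep(list(delegate_policy(tb72)), 4), crd_config(), seed = 1)
  expect_true(all(g72$contributions[1:9, ] == 2))
  expect_true(all(g72$contributions[10, ] == 0))

  # switch 0: strategy2 active from round 2 onward regardless of play
  tb0 <- strategy_table(2, c(2, 2, 2), 0, c(4, 4, 4))
  g0 <- play_game(rep(list(delegate_policy(tb0)), 4), crd_config(), seed = 1)
  expect_true(all(g0$contributions[1, ] == 2))
  expect_true(all(g0$contributions[-1, ] == 4))
})

test_that("reaction tables are evaluated at the rounded others' average", {
  # others contributed (4, 4, 0): average 8/3 ~ 2.67 snaps to 2 in {0,2,4}
  tb <- strategy_table(2, c(4, 2, 0), 120, c(0, 0, 0))
  pol <- delegate_policy(tb)
  expect_equal(pol(2, mean(c(4, 4, 0)), 8), 2)
  # the agent's own contribution is excluded from the average by play_game:
  # one reactive agent among three constant-4 players sees average 4
  reactive <- strategy_table(0, c(0, 2, 4), 120, c(0, 2, 4))
  g <- play_game(
    c(list(delegate_policy(reactive)), rep(list(constant_policy(4)), 3)),
    crd_config(), seed = 1
  )
  expect_equal(g$contributions[, 1], c(0, rep(4, 9)))
})

test_that("classify_table distinguishes conditional and fixed programs", {
  expect_equal(
    classify_table(strategy_table(2, c(2, 2, 2), 80, c(2, 2, 2))),
    tibble::tibble(strategy1_constant = TRUE, fully_constant = TRUE)
  )
  expect_equal(
    classify_table(strategy_table(4, c(4, 4, 4), 80, c(0, 4, 4))),
    tibble::tibble(strategy1_constant = TRUE, fully_constant = FALSE)
  )
  # same constant in both strategies but a different starting action is
  # not a truly fixed behavior
  expect_false(
    classify_table(strategy_table(0, c(2, 2, 2), 80, c(2, 2, 2)))$fully_constant
  )
  expect_equal(
    classify_table(strategy_table(2, c(0, 2, 4), 80, c(0, 2, 4))),
    tibble::tibble(strategy1_constant = FALSE, fully_constant = FALSE)
  )
})

test_that("delegate semantics agree with a brute-force interpreter on sampled programs", {
  # random 3- and 5-choice programs with random switch values, replayed in
  # groups of four random programs against the independent interpreter
  # (the exhaustive 3-choice sweep runs in the acceptance suite)
  withr::with_seed(17, {
    for (i in 1:60) {
      space <- if (i %% 2) space3 else space5
      cfg <- crd_config(action_space = space)
      tables <- replicate(4, strategy_table(
        sample(space, 1), sample(space, length(space), replace = TRUE),
        sample(0:120, 1), sample(space, length(space), replace = TRUE),
        action_space = space
      ), simplify = FALSE)
      played <- play_game(lapply(tables, delegate_policy, config = cfg),
                          cfg, seed = i)
      expect_identical(unname(played$contributions),
                       unname(interpret_delegates(tables)))
    }
  })
})

test_that("monotone tables give responses monotone in the rounded average", {
  withr::with_seed(7, {
    for (i in 1:20) {
      entries <- sort(sample(space5, 5, replace = TRUE))
      tb <- strategy_table(2, entries, 120, entries, action_space = space5)
      pol <- delegate_policy(tb, crd_config(action_space = 0:4))
      resp <- vapply(seq(0, 4, by = 0.5), function(avg) pol(2, avg, 10),
                     numeric(1))
      expect_true(all(diff(resp) >= 0))
    }
  })
})

test_that("tables serialize to one flat row per program", {
  tb <- strategy_table(2, c(0, 2, 4), 60, c(0, 0, 0))
  row <- tables_to_tibble(tb)
  expect_equal(
    names(row),
    c("start", "s1_at_0", "s1_at_2", "s1_at_4", "switch",
      "s2_at_0", "s2_at_2", "s2_at_4")
  )
  expect_equal(row$switch, 60)
  expect_equal(unlist(row[paste0("s1_at_", c(0, 2, 4))], use.names = FALSE),
               c(0, 2, 4))
})
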