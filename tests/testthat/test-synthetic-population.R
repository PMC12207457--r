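test_that("noiseless profile policies realize their target sequences", {
  fair <- profile_policy(behavior_profile("fair", noise_sd = 0), c(0, 2, 4))
  expect_equal(vapply(1:10, fair, numeric(1), NA, 0), rep(2, 10))

  early <- profile_policy(behavior_profile("early", noise_sd = 0), c(0, 2, 4))
  acts <- vapply(1:10, early, numeric(1), NA, 0)
  expect_gt(mean(acts[1:5]), 2)
  expect_lt(mean(acts[6:10]), 2)
  expect_equal(acts, c(rep(4, 5), rep(0, 5)))

  # a low contributor with target 1 under 5 choices is selfish without
  # ever contributing zero
  low1 <- profile_policy(
    behavior_profile("low", targets = rep(1, 10), noise_sd = 0), 0:4
  )
  expect_equal(vapply(1:10, low1, numeric(1), NA, 0), rep(1, 10))

  # the default low target snaps to 0 under 3 choices but 1 under 5
  low <- behavior_profile("low", noise_sd = 0)
  expect_equal(profile_policy(low, c(0, 2, 4))(1, NA, 0), 0)
  expect_equal(profile_policy(low, 0:4)(1, NA, 0), 1)
})

test_that("noise draws are made at creation: policies are reproducible", {
  p1 <- profile_policy(behavior_profile("fair"), 0:4, seed = 5)
  p2 <- profile_policy(behavior_profile("fair"), 0:4, seed = 5)
  expect_identical(vapply(1:10, p1, numeric(1), NA, 0),
                   vapply(1:10, p2, numeric(1), NA, 0))
})

test_that("sampled fair tables replay to all-2 against fair opponents", {
  for (seed in 1:10) {
    tb <- sample_strategy_table(behavior_profile("fair"), c(0, 2, 4),
                                seed = seed)
    g <- play_game(rep(list(delegate_policy(tb)), 4), crd_config(),
                   seed = seed)
    expect_true(all(g$contributions == 2))
    expect_equal(g$final_public_account, 80)
  }
})

test_that("early tables encode the drop through the switch", {
  for (seed in 1:10) {
    tb <- sample_strategy_table(behavior_profile("early"), c(0, 2, 4),
                                seed = seed)
    expect_lte(tb$switch_value, 80)
    # strategy 2 contributes less than strategy 1 at the middle key
    expect_lt(tb$strategy2[["2"]], tb$strategy1[["2"]])
    # replayed against fair companions the agent front-loads then drops
    companions <- replicate(3, sample_strategy_table(
      behavior_profile("fair"), c(0, 2, 4), seed = seed + 100
    ), simplify = FALSE)
    g <- play_game(
      lapply(c(list(tb), companions), delegate_policy), crd_config(), seed = 1
    )
    own <- g$contributions[, 1]
    expect_gt(mean(own[1:5]), mean(own[6:10]))
  }
})

test_that("conditional-probability 0 yields truly fixed programs", {
  tb <- sample_strategy_table(behavior_profile("fair"), c(0, 2, 4),
                              seed = 3, p_conditional = 0)
  expect_true(classify_table(tb)$fully_constant)
  # and by default most programs are conditional
  n_cond <- sum(vapply(1:200, function(s) {
    !classify_table(
      sample_strategy_table(behavior_profile("fair"), c(0, 2, 4), seed = s)
    )$strategy1_constant
  }, logical(1)))
  expect_gte(n_cond / 200, 0.8)
})

test_that("generate_study produces the full factorial bookkeeping", {
  st <- generate_study(study_design(n_groups = 10, seed = 11))
  expect_equal(length(unique(st$player_id)), 160)
  expect_equal(nrow(dplyr::distinct(st, player_id, game)), 320)
  expect_equal(nrow(st), 160 * 2 * 10)
  expect_equal(nrow(dplyr::count(st, treatment_choices, treatment_delegation)), 4)
  # delegate tables exist exactly for delegation cells, one row per
  # player-game
  tables <- study_tables(st)
  deleg_players <- unique(st$player_id[st$treatment_delegation])
  expect_setequal(unique(tables$player_id), deleg_players)
  expect_equal(nrow(tables), length(deleg_players) * 2)
})

test_that("generation is byte-identical under a fixed design and seed", {
  d <- study_design(n_groups = 3, seed = 21)
  expect_identical(generate_study(d), generate_study(d))
  d2 <- study_design(n_groups = 3, seed = 22)
  expect_false(identical(generate_study(d), generate_study(d2)))
})

test_that("an all-fair noiseless population without revision hits the target in both games", {
  mix <- default_mixtures()
  mix$early <- 0; mix$high <- 0; mix$low <- 0; mix$fair <- 1
  d <- study_design(
    n_groups = 4, mixtures = mix, noise_sd = 0,
    revision = revision_params(0, 0, 0), seed = 5
  )
  gm <- group_metrics(generate_study(d))
  expect_true(all(gm$final_public_account == 80))
  expect_true(all(gm$success))
})

test_that("revision with zero parameters is the identity", {
  m <- make_member(behavior_profile("high"), delegation = TRUE,
                   space = c(0, 2, 4), seed = 9)
  expect_identical(
    revise_behavior(m, group_success = FALSE, params = revision_params(0, 0, 0),
                    seed = 1),
    m
  )
  m2 <- make_member(behavior_profile("fair"), delegation = FALSE,
                    space = c(0, 2, 4), seed = 9)
  expect_identical(
    revise_behavior(m2, group_success = FALSE,
                    params = revision_params(0, 0, 0), seed = 1),
    m2
  )
})

test_that("forced give-up sends failed no-delegation members to zero", {
  m <- make_member(behavior_profile("fair", noise_sd = 0), delegation = FALSE,
                   space = c(0, 2, 4), seed = 9)
  rev <- revise_behavior(m, group_success = FALSE,
                         params = revision_params(p_giveup = 1), seed = 1)
  pol <- profile_policy(rev$profile, c(0, 2, 4))
  expect_equal(vapply(1:10, pol, numeric(1), NA, 0), rep(0, 10))
})

test_that("delegation members of failed groups shift their programs upward", {
  m <- make_member(behavior_profile("low", noise_sd = 0), delegation = TRUE,
                   space = c(0, 2, 4), seed = 2)
  rev <- revise_behavior(m, group_success = FALSE,
                         params = revision_params(delta_up = 1), seed = 1)
  expect_true(all(rev$profile$targets >= m$profile$targets))
  expect_gte(rev$table$strategy1[["2"]], m$table$strategy1[["2"]])
  # replay both against fair companions: the revised program contributes more
  companions <- replicate(3, sample_strategy_table(
    behavior_profile("fair"), c(0, 2, 4), seed = 50
  ), simplify = FALSE)
  before <- play_game(lapply(c(list(m$table), companions), delegate_policy),
                      crd_config(), seed = 1)
  after <- play_game(lapply(c(list(rev$table), companions), delegate_policy),
                     crd_config(), seed = 1)
  expect_gt(sum(after$contributions[, 1]), sum(before$contributions[, 1]))
})

test_that("noiseless no-delegation populations are recovered by the clustering", {
  mix <- default_mixtures() |> dplyr::filter(!delegation)
  mix$early <- 0.25; mix$high <- 0.25; mix$fair <- 0.25; mix$low <- 0.25
  d <- study_design(
    n_groups = 15, mixtures = mix, noise_sd = 0,
    revision = revision_params(0, 0, 0), seed = 31
  )
  st <- generate_study(d)
  labels <- label_behaviors(st, k = 4, seed = 1)
  truth <- study_profiles(st)
  joined <- dplyr::inner_join(labels, truth, by = c("player_id", "game"))
  expect_gte(mean(joined$behavior == joined$label), 0.95)
})

test_that("revision moves outcomes in the observed directions", {
  deltas <- purrr::map_dfr(1:5, function(s) {
    st <- generate_study(study_design(n_groups = 10, seed = 100 + s))
    study_deltas(st)
  })
  fail_deleg <- dplyr::filter(deltas, treatment_delegation, !game1_success)
  expect_gt(mean(fail_deleg$delta), 0)
  # failed no-delegation groups contribute less in Game 2
  fail_nodeleg <- dplyr::filter(deltas, !treatment_delegation, !game1_success)
  expect_lt(mean(fail_nodeleg$delta), 0)
})
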