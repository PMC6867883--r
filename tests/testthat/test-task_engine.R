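test_that("design presets carry the published trial arithmetic", {
  d1 <- build_design("study1")
  expect_identical(d1$n_trials, 200L)
  expect_identical(d1$blocks, 2L)
  expect_identical(d1$nc_per_domain, 0L)
  d1r <- build_design("study1R")
  expect_identical(d1r$n_trials, 100L)
  d2 <- build_design("study2")
  expect_identical(d2$n_trials, 140L)
  expect_identical(d2$blocks * 2L * d2$nc_per_domain, 40L)
  expect_error(build_design("study3"), "arg")
})

test_that("block schedules balance rewards and sides", {
  d2 <- build_design("study2")
  set.seed(50)
  sched <- schedule_block(d2, 1)
  expect_identical(nrow(sched), 28L)
  for (dom in c("math", "word")) {
    ch <- sched[!sched$is_no_choice & sched$domain == dom, ]
    # 10 choice trials: each hard reward value appears exactly twice
    expect_identical(as.integer(table(factor(ch$hard_reward, levels = 2:6))),
                     rep(2L, 5))
    expect_lte(abs(sum(ch$hard_side == "left") -
                     sum(ch$hard_side == "right")), 1L)
    nc <- sched[sched$is_no_choice & sched$domain == dom, ]
    expect_identical(sort(nc$forced_option), c("easy", "easy", "hard", "hard"))
    expect_true(all(nc$hard_reward[nc$forced_option == "hard"] == 5L))
  }
  # schedules are seed-deterministic
  set.seed(50); a <- schedule_block(d2, 1)
  set.seed(50); b <- schedule_block(d2, 1)
  expect_identical(a, b)
})

test_that("sessions emit the exact trial counts per study", {
  bank <- test_bank()
  ag <- agent_params()
  for (spec in list(c("study1", 200L), c("study1R", 100L),
                    c("study2", 140L))) {
    log <- run_session(ag, build_design(spec[1]), bank, seed = 60)
    main <- log[!log$is_practice, ]
    expect_identical(nrow(main), as.integer(spec[2]))
  }
})

test_that("an always-timeout agent yields all 1-cent level-1 fallbacks", {
  ag <- agent_params(timeout_prob = 1)
  log <- run_session(ag, build_design("study1R"), test_bank(), seed = 61,
                     include_practice = FALSE)
  expect_true(all(log$choice == "timeout"))
  expect_true(all(log$difficulty_level == 1L))
  expect_true(all(log$choice_rt == 3))
  expect_true(all(log$reward_earned %in% c(0L, 1L)))
  expect_true(all(log$reward_earned[log$solve_correct] == 1L))
})

test_that("an always-correct always-hard agent rides the staircase to 7", {
  ag <- ev_agent(competence_math = 1e6, competence_word = 1e6, lapse = 0,
                 perceived_acc_hard = 1, rt_solve_meanlog = log(2),
                 rt_solve_sdlog = 0.01)
  log <- run_session(ag, build_design("study2"), test_bank(), seed = 62,
                     include_practice = FALSE)
  hard_m <- log[log$choice == "hard" & log$domain == "math", ]
  # hand-traced 2-up-1-down under all-correct: 4,4,5,5,6,6,7,7,...
  expect_identical(hard_m$difficulty_level[1:8],
                   c(4L, 4L, 5L, 5L, 6L, 6L, 7L, 7L))
  expect_true(all(hard_m$difficulty_level[9:nrow(hard_m)] == 7L))
})

test_that("reward conservation: log re-tally matches reward_earned", {
  log <- run_session(agent_params(), build_design("study2"), test_bank(),
                     seed = 63)
  main <- log[!log$is_practice, ]
  chosen_value <- ifelse(main$choice == "timeout", 1L,
                  ifelse(main$choice == "hard", main$hard_reward_offered, 2L))
  expect_identical(sum(main$reward_earned),
                   sum(chosen_value[main$solve_correct]))
  expect_true(all(log$reward_earned[log$is_practice] == 0L))
})

test_that("session invariants: levels, lockout, forced exposure", {
  bank <- test_bank()
  # even an agent that never picks hard solves >= 10 hard per domain in
  # study 2, thanks to the no-choice trials
  avoider <- agent_params(cost_base_math = 50, cost_base_word = 50,
                          timeout_prob = 0)
  log <- run_session(avoider, build_design("study2"), bank, seed = 64,
                     include_practice = FALSE)
  for (dom in c("math", "word")) {
    hard <- log[log$domain == dom & log$choice == "hard", ]
    expect_gte(nrow(hard), 10L)
    expect_true(all(hard$difficulty_level >= 2L &
                      hard$difficulty_level <= 7L))
  }
  expect_true(all(log$difficulty_level[log$choice != "hard"] == 1L))
  expect_true(all(is.na(log$solve_rt) | log$solve_rt >= 1.5))
  # no-choice trials never time out in the choose phase
  expect_false(any(log$choice[log$is_no_choice] == "timeout"))

  # determinism: same seed, identical log
  a <- run_session(agent_params(), build_design("study1R"), bank, seed = 65)
  b <- run_session(agent_params(), build_design("study1R"), bank, seed = 65)
  expect_identical(a, b)
})
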