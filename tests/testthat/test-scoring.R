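test_that("expected value is reward times accuracy", {
  expect_identical(expected_value(4, 0.7), 2.8)   # the hard 4-cent card
  expect_identical(expected_value(2, 0.95), 1.9)  # the easy card
  expect_identical(expected_value(6, 0), 0)
  expect_error(expected_value(-1, 0.5))
  expect_error(expected_value(4, 1.2))
})

test_that("HCP follows the mean-of-conditions definition", {
  fx <- make_fixtures(seed = 1)
  log <- fx$hcp_log
  # hand computation: cells 4/5/6 cents hold 2/3/4 trials with 2/1/1 hard
  expect_equal(compute_hcp(log, "math"), (1 + 1/3 + 1/4) / 3)
  expect_equal(compute_hcp(log, "math"), 19 / 36)
  # the pooled form differs on this unbalanced log
  expect_equal(compute_hcp(log, "math", method = "pooled"), 4 / 9)

  # always-hard participant scores 1.0
  all_hard <- log
  all_hard$choice <- "hard"
  expect_equal(compute_hcp(all_hard, "math"), 1.0)

  # equal cells with proportions (1, 0.5, 0) average to 0.5
  log2 <- log[c(1, 2, 3, 4, 6, 7), ]
  log2$hard_reward_offered <- c(4L, 4L, 5L, 5L, 6L, 6L)
  log2$choice <- c("hard", "hard", "hard", "easy", "easy", "easy")
  expect_equal(compute_hcp(log2, "math"), 0.5)

  # an empty cell is an error naming the cell
  expect_error(compute_hcp(log[log$hard_reward_offered != 5, ], "math"),
               "5-cent")
  expect_error(compute_hcp(log, "word"), "word")
})

test_that("HCP ignores practice, no-choice, and timeout trials", {
  fx <- make_fixtures(seed = 1)
  log <- fx$hcp_log
  extra <- log[c(1, 1, 1), ]
  extra$choice <- c("hard", "hard", "timeout")
  extra$is_practice <- c(TRUE, FALSE, FALSE)
  extra$is_no_choice <- c(FALSE, TRUE, FALSE)
  expect_equal(compute_hcp(rbind(log, extra), "math"), 19 / 36)
})

test_that("ADL is the mean level of hard problems encountered", {
  fx <- make_fixtures(seed = 1)
  log <- fx$hcp_log[fx$hcp_log$choice == "hard", ]
  log$difficulty_level <- c(4L, 5L, 5L, 6L)
  expect_equal(compute_adl(log, "math"), 5.0)
  log$difficulty_level <- rep(4L, 4)
  expect_equal(compute_adl(log, "math"), 4.0)
  expect_error(compute_adl(log[0, ], "math"), "no hard")
})

test_that("no-choice hard trials enter ADL", {
  fx <- make_fixtures(seed = 1)
  log <- fx$hcp_log[fx$hcp_log$choice == "hard", ]
  log$difficulty_level <- c(4L, 4L, 4L, 4L)
  nc <- log[1, ]
  nc$is_no_choice <- TRUE
  nc$difficulty_level <- 6L
  expect_equal(compute_adl(rbind(log, nc), "math"), (4 * 4 + 6) / 5)
})

test_that("competence orders ADL on a common design and seed grid", {
  bank <- test_bank()
  d <- build_design("study2")
  strong <- ev_agent(competence_math = 6, competence_word = 6)
  weak <- ev_agent(competence_math = 3, competence_word = 3)
  adl <- function(agent) {
    mean(vapply(1:5, function(s) {
      compute_adl(run_session(agent, d, bank, seed = 100 + s), "math")
    }, numeric(1)))
  }
  expect_gt(adl(strong), adl(weak))
})

test_that("the exclusion rule keeps 4 of the 6 toy participants", {
  fx <- make_fixtures(seed = 1)
  parts <- apply_exclusions(fx$exclusion_summaries)
  expect_identical(nrow(parts$kept), 4L)
  expect_identical(nrow(parts$excluded), 2L)
  # strictly-below-70% boundary: 0.70 stays, 0.69 goes
  expect_true("fx04" %in% parts$kept$participant_id)    # 0.70
  expect_true("fx03" %in% parts$excluded$participant_id) # 0.69
  expect_identical(nrow(parts$kept) + nrow(parts$excluded),
                   nrow(fx$exclusion_summaries))

  # undefined easy accuracy excludes, with a warning
  na_sum <- fx$exclusion_summaries
  na_sum$math_easy_accuracy[1] <- NA_real_
  expect_warning(parts2 <- apply_exclusions(na_sum), "undefined")
  expect_identical(nrow(parts2$kept), 3L)
})

test_that("timeout proportion counts hard solve timeouts", {
  fx <- make_fixtures(seed = 1)
  log <- fx$hcp_log[fx$hcp_log$choice == "hard", ]
  expect_equal(timeout_proportion(log, "math"), 0.0)
  log10 <- log[rep(1, 10), ]
  log10$solve_timeout <- c(rep(TRUE, 2), rep(FALSE, 8))
  expect_equal(timeout_proportion(log10, "math"), 0.2)
})

test_that("slow agents time out more than fast agents", {
  bank <- test_bank()
  d <- build_design("study2")
  fast <- agent_params(rt_solve_meanlog = log(3), rt_solve_sdlog = 0.2)
  slow <- agent_params(rt_solve_meanlog = log(6.5), rt_solve_sdlog = 0.4)
  tp <- function(agent) {
    log <- run_session(agent, d, bank, seed = 111)
    timeout_proportion(log[!log$is_practice, ], "math")
  }
  expect_gt(tp(slow), tp(fast))
})

test_that("block slopes: constant series give 0, linear series give 1", {
  blocks <- data.frame(participant_id = "p1", block = 1:5,
                       math_hcp = rep(0.6, 5), word_hcp = 1:5,
                       math_adl = c(4, 4, 4, 4, 4), word_adl = 5:1)
  res <- block_slopes(blocks)
  expect_equal(res$slopes$math_hcp, 0)
  expect_equal(res$slopes$word_hcp, 1)
  expect_equal(res$slopes$word_adl, -1)
  expect_error(block_slopes(blocks[1, ]), "2 blocks")
})

test_that("a stationary cohort has near-zero mean block slopes", {
  cfg <- cohort_config(40, seed = 120)
  agents <- traits_to_agents(generate_traits(cfg), seed = 121)
  log <- run_cohort(agents, build_design("study1R"), bank = test_bank(),
                    seed = 122)
  res <- block_slopes(block_measures(log))
  adl <- res$cohort[res$cohort$measure == "math_adl", ]
  # agents have no learning/fatigue dynamics: slope should hover near 0
  expect_lt(abs(adl$mean_slope), 0.15)
  expect_gt(adl$sign_test_p, 0.01)
})

test_that("summaries populate per-domain measures and exclusion flags", {
  log <- run_session(agent_params(), build_design("study2"), test_bank(),
                     seed = 130)
  s <- summarize_participants(log)
  expect_identical(nrow(s), 1L)
  expect_true(s$math_hcp >= 0 && s$math_hcp <= 1)
  expect_true(s$math_adl >= 2 && s$math_adl <= 7)
  expect_true(s$word_adl >= 2 && s$word_adl <= 7)
  expect_true(all(c("math_easy_accuracy", "word_hard_rt",
                    "math_hard_timeout", "excluded") %in% names(s)))
  expect_false(s$excluded)
})
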