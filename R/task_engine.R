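# Session execution.
#
# A session is a sequence of trials, each with a choose phase (easy card,
# always 2 cents, vs hard card, 2-6 cents; 3 s to decide, lapse -> easy
# level-1 problem worth 1 cent), a solve phase (7 s limit, responses
# locked out for the first 1.5 s), and feedback (reward credited only on
# a correct solve). Hard-problem difficulty follows one 2-up-1-down
# staircase per domain, persisting from the practice block onward.

#' Build a session design preset
#'
#' The three study layouts:
#' \itemize{
#'   \item \code{study1}: 2 blocks x (50 math + 50 word) choice trials,
#'     200 trials, no forced trials.
#'   \item \code{study1R}: 5 blocks x (10 + 10), 100 trials (the retest
#'     design).
#'   \item \code{study2}: 5 blocks x (10 + 10 choice, plus 4 no-choice
#'     math and 4 no-choice word), 140 trials; the 40 no-choice trials
#'     split 10/10/10/10 over (easy, hard) x (math, word) and guarantee
#'     minimum exposure to both problem types.
#' }
#' The practice block mirrors a main block (20 trials for study1/1R, 28
#' for study2), advances the staircases, and pays nothing.
#'
#' @param study One of \code{"study1"}, \code{"study1R"}, \code{"study2"}.
#' @return An object of class \code{session_design}.
#' @examples
#' d <- build_design("study2")
#' d$n_trials  # 140
#' @export
build_design <- function(study = c("study1", "study1R", "study2")) {
  study <- match.arg(study)
  cfg <- switch(study,
    study1  = list(blocks = 2L, choice_per_domain = 50L, nc_per_domain = 0L),
    study1R = list(blocks = 5L, choice_per_domain = 10L, nc_per_domain = 0L),
    study2  = list(blocks = 5L, choice_per_domain = 10L, nc_per_domain = 4L))
  per_block <- 2L * cfg$choice_per_domain + 2L * cfg$nc_per_domain
  structure(list(
    study = study,
    blocks = cfg$blocks,
    choice_per_domain = cfg$choice_per_domain,  # choice trials per domain/block
    nc_per_domain = cfg$nc_per_domain,          # no-choice per domain/block
    n_trials = cfg$blocks * per_block,
    hard_rewards = 2:6,
    easy_reward = 2L,
    nc_easy_reward = 2L,
    nc_hard_reward = 5L,
    timeout_fallback_reward = 1L,
    choose_limit = 3, solve_limit = 7, response_lockout = 1.5,
    # practice mirrors a main block shape at 10 choice trials per domain:
    # 20 trials for study1/1R, 28 for study2
    practice_choice_per_domain = 10L,
    practice_trials = 2L * (10L + cfg$nc_per_domain)
  ), class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> %s: %d blocks, %d trials (%d no-choice)\n",
              x$study, x$blocks, x$n_trials,
              x$blocks * 2L * x$nc_per_domain))
  invisible(x)
}

# balanced assignment of n hard rewards over {2..6}: equal counts,
# remainder assigned at random
.balanced_rewards <- function(n, values = 2:6) {
  k <- length(values)
  out <- rep(values, n %/% k)
  rem <- n %% k
  if (rem > 0L) out <- c(out, sample(values, rem))
  sample(out)
}

# left/right counterbalance: half left, half right (+-1 for odd n)
.balanced_sides <- function(n) {
  sides <- rep(c("left", "right"), length.out = n)
  sample(sides)
}

#' Schedule the offers of one block
#'
#' Lays out every trial of a block as a \code{ChoiceOffer} row: hard
#' rewards balanced over \{2,...,6\} within domain (equal counts when the
#' count divides by five, remainder randomised), hard-card side
#' counterbalanced, no-choice trials (if any) split evenly between forced
#' easy and forced hard, and the whole block order shuffled. Consumes the
#' current R random stream.
#'
#' @param design A \code{session_design}.
#' @param block_index 1-based block number; 0 schedules the (smaller)
#'   practice block.
#' @return data.frame with columns \code{domain}, \code{is_no_choice},
#'   \code{forced_option}, \code{easy_reward}, \code{hard_reward},
#'   \code{hard_side}.
#' @export
schedule_block <- function(design, block_index) {
  stopifnot(inherits(design, "session_design"))
  n_choice <- if (block_index == 0L) design$practice_choice_per_domain
    else design$choice_per_domain
  offers <- list()
  for (dom in c("math", "word")) {
    n <- n_choice
    offers[[paste0(dom, ".choice")]] <- data.frame(
      domain = dom, is_no_choice = FALSE, forced_option = NA_character_,
      easy_reward = design$easy_reward,
      hard_reward = .balanced_rewards(n, design$hard_rewards),
      hard_side = .balanced_sides(n),
      stringsAsFactors = FALSE)
    if (design$nc_per_domain > 0L) {
      n_nc <- design$nc_per_domain
      forced <- sample(rep(c("easy", "hard"), length.out = n_nc))
      offers[[paste0(dom, ".nc")]] <- data.frame(
        domain = dom, is_no_choice = TRUE, forced_option = forced,
        easy_reward = design$nc_easy_reward,
        hard_reward = ifelse(forced == "hard",
                             design$nc_hard_reward, NA_integer_),
        hard_side = .balanced_sides(n_nc),
        stringsAsFactors = FALSE)
    }
  }
  block <- do.call(rbind, offers)
  block <- block[sample.int(nrow(block)), , drop = FALSE]
  rownames(block) <- NULL
  block
}

#' Simulate one full session
#'
#' Runs an agent through the practice block (if enabled) and all main
#' blocks of a design against a problem bank, and returns the trial log.
#' Easy solves always draw level-1 problems; hard solves draw at the
#' domain's current staircase level (initialised at 4, bounds \[2, 7\])
#' and update it, whether chosen or forced; a choose-phase timeout routes
#' to a level-1 problem worth 1 cent. Deterministic given \code{seed}.
#'
#' @param agent An \code{agent_params}.
#' @param design A \code{session_design}.
#' @param bank A \code{problem_bank} covering level 1 and levels 2-7 in
#'   both domains.
#' @param seed Integer seed for the whole session.
#' @param include_practice Run the warm-up block (default \code{TRUE});
#'   its records carry \code{is_practice = TRUE}, \code{block_index = 0},
#'   earn no reward, and are excluded from scoring by default.
#' @return data.frame of trial records, one row per trial, with columns
#'   \code{participant_id}, \code{study}, \code{block_index},
#'   \code{trial_index}, \code{is_practice}, \code{domain},
#'   \code{is_no_choice}, \code{hard_reward_offered}, \code{choice},
#'   \code{choice_rt}, \code{difficulty_level}, \code{problem_id},
#'   \code{solve_correct}, \code{solve_rt}, \code{solve_timeout},
#'   \code{reward_earned}.
#' @export
run_session <- function(agent, design, bank, seed,
                        include_practice = TRUE) {
  stopifnot(inherits(agent, "agent_params"),
            inherits(design, "session_design"),
            inherits(bank, "problem_bank"))
  set.seed(as.integer(seed))

  # required cells must exist up front
  for (dom in c("math", "word")) {
    for (lv in 1:7) {
      if (!length(.bank_cell(bank, dom, lv))) {
        stop(sprintf("bank lacks items for (%s, level %d)", dom, lv),
             call. = FALSE)
      }
    }
  }

  lat <- bank$problems$latent_difficulty
  ids <- bank$problems$id

  blocks <- if (include_practice) c(0L, seq_len(design$blocks)) else
    seq_len(design$blocks)
  n_total <- design$n_trials +
    if (include_practice) design$practice_trials else 0L

  # full schedule up front, as plain vectors
  scheds <- lapply(blocks, function(b) schedule_block(design, b))
  n_by_block <- vapply(scheds, nrow, integer(1))
  sched <- do.call(rbind, scheds)
  s_dom_word <- sched$domain == "word"
  s_nc <- sched$is_no_choice
  s_forced_hard <- !is.na(sched$forced_option) &
    sched$forced_option == "hard"
  s_hard_reward <- sched$hard_reward
  s_easy_reward <- sched$easy_reward
  block_index <- rep(blocks, n_by_block)
  trial_index <- unlist(lapply(n_by_block, seq_len), use.names = FALSE)
  is_practice <- block_index == 0L

  # pre-drawn randomness, consumed one slot per trial
  u_timeout <- stats::runif(n_total)
  u_choice <- stats::runif(n_total)
  u_correct <- stats::runif(n_total)
  crt_draw <- pmin(stats::rlnorm(n_total, agent$rt_choose_meanlog,
                                 agent$rt_choose_sdlog),
                   design$choose_limit)
  srt_norm <- stats::rlnorm(n_total, agent$rt_solve_meanlog,
                            agent$rt_solve_sdlog)
  srt_guess <- stats::rlnorm(n_total, agent$rt_guess_meanlog,
                             agent$rt_guess_sdlog)

  # lookup tables: P(hard) by (domain, reward 2..6, level 1..7); accuracy
  # per bank item; guessing cutoff level per domain
  p_hard <- array(NA_real_, c(2, 5, 7))
  for (di in 1:2) for (ri in 1:5) for (li in 1:7) {
    p_hard[di, ri, li] <- choice_prob_hard(
      agent, c("math", "word")[di], design$easy_reward, ri + 1L, li)
  }
  acc_item <- ifelse(bank$problems$domain == "math",
                     solve_accuracy(agent, "math", lat),
                     solve_accuracy(agent, "word", lat))
  guess_cut <- vapply(c("math", "word"), function(d) {
    cpl <- .cost_per_level(agent, d)
    if (cpl <= 0 || !is.finite(agent$guess_threshold)) Inf
    else agent$guess_threshold / cpl
  }, numeric(1))

  # without-replacement draw state, one permutation per (domain, level)
  draw_order <- vector("list", 14L)
  draw_ptr <- integer(14L)
  for (di in 1:2) for (li in 1:7) {
    k <- (di - 1L) * 7L + li
    draw_order[[k]] <- sample(.bank_cell(bank, c("math", "word")[di], li))
  }

  # per-domain staircase registers (2-up-1-down, bounds [2,7], start 4);
  # staircase_update() is the reference implementation of the same rule
  st_level <- c(4L, 4L)
  st_streak <- c(0L, 0L)

  is_no_choice <- s_nc
  hard_reward_offered <- ifelse(is.na(s_hard_reward), NA_integer_,
                                as.integer(s_hard_reward))
  domain <- ifelse(s_dom_word, "word", "math")
  choice <- character(n_total); choice_rt <- numeric(n_total)
  difficulty_level <- integer(n_total); pick_idx <- integer(n_total)
  solve_correct <- logical(n_total); solve_rt <- numeric(n_total)
  solve_timeout <- logical(n_total); reward_earned <- integer(n_total)

  for (i in seq_len(n_total)) {
    di <- if (s_dom_word[i]) 2L else 1L
    lvl_now <- st_level[di]

    if (s_nc[i]) {
      ch <- if (s_forced_hard[i]) "hard" else "easy"
      crt <- crt_draw[i]
      offered <- if (s_forced_hard[i]) s_hard_reward[i] else s_easy_reward[i]
    } else if (u_timeout[i] < agent$timeout_prob) {
      ch <- "timeout"
      crt <- design$choose_limit
      offered <- design$timeout_fallback_reward
    } else {
      ri <- s_hard_reward[i] - 1L
      ch <- if (u_choice[i] < p_hard[di, ri, lvl_now]) "hard" else "easy"
      crt <- crt_draw[i]
      offered <- if (ch == "hard") s_hard_reward[i] else s_easy_reward[i]
    }

    lv <- if (ch == "hard") lvl_now else 1L
    k <- (di - 1L) * 7L + lv
    ptr <- draw_ptr[k] + 1L
    if (ptr > length(draw_order[[k]])) {   # cell exhausted: reshuffle
      draw_order[[k]] <- sample(draw_order[[k]])
      ptr <- 1L
    }
    draw_ptr[k] <- ptr
    pick <- draw_order[[k]][ptr]

    guess <- lv > guess_cut[di]
    srt <- if (guess) srt_guess[i] else srt_norm[i]
    if (srt > design$solve_limit) {
      s_timeout <- TRUE
      correct <- FALSE
      srt <- NA_real_
    } else {
      s_timeout <- FALSE
      srt <- max(srt, design$response_lockout)
      p_correct <- if (guess) 1 / 3 else acc_item[pick]
      correct <- u_correct[i] < p_correct
    }

    if (ch == "hard") {                    # 2-up-1-down update
      if (correct) {
        if (st_streak[di] >= 1L) {
          st_level[di] <- min(lvl_now + 1L, 7L)
          st_streak[di] <- 0L
        } else st_streak[di] <- 1L
      } else {
        st_level[di] <- max(lvl_now - 1L, 2L)
        st_streak[di] <- 0L
      }
    }

    choice[i] <- ch; choice_rt[i] <- crt
    difficulty_level[i] <- lv; pick_idx[i] <- pick
    solve_correct[i] <- correct
    solve_rt[i] <- srt
    solve_timeout[i] <- s_timeout
    reward_earned[i] <- if (correct && !is_practice[i]) as.integer(offered)
      else 0L
  }
  problem_id <- ids[pick_idx]

  data.frame(
    participant_id = agent$id, study = design$study,
    block_index = block_index, trial_index = trial_index,
    is_practice = is_practice, domain = domain,
    is_no_choice = is_no_choice,
    hard_reward_offered = hard_reward_offered,
    choice = choice, choice_rt = round(choice_rt, 3),
    difficulty_level = difficulty_level, problem_id = problem_id,
    solve_correct = solve_correct, solve_rt = round(solve_rt, 3),
    solve_timeout = solve_timeout, reward_earned = reward_earned,
    stringsAsFactors = FALSE
  )
}

#' Simulate a whole cohort
#'
#' Runs \code{run_session} for every agent, with per-agent seeds derived
#' from \code{seed}, and row-binds the logs.
#'
#' @param agents List of \code{agent_params}.
#' @param design A \code{session_design}.
#' @param bank A \code{problem_bank}; a default bank is generated when
#'   omitted.
#' @param seed Integer master seed.
#' @param include_practice Passed to \code{\link{run_session}}.
#' @return Combined trial-log data.frame.
#' @export
run_cohort <- function(agents, design, bank = NULL, seed = 1,
                       include_practice = TRUE) {
  if (is.null(bank)) bank <- generate_bank(700, 700, seed = seed)
  seeds <- .derive_seeds(seed, length(agents))
  logs <- vector("list", length(agents))
  for (j in seq_along(agents)) {
    logs[[j]] <- run_session(agents[[j]], design, bank, seed = seeds[j],
                             include_practice = include_practice)
  }
  do.call(rbind, logs)
}

# deterministic 32-bit sub-seeds from one master seed
.derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}
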