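# Generative agent model.
#
# An agent is (i) a psychometric solver: accuracy is a logistic function of
# competence minus latent item difficulty, with a 1/3 guessing floor (three
# answer options) and a lapse-limited ceiling; (ii) a cost-benefit chooser:
# each card gets a subjective value = believed accuracy x reward - effort
# cost, and the hard card is chosen by a softmax on the value difference.
# Math effort cost grows with math anxiety, which is the package's whole
# hypothesis machinery: anxious agents discount hard math, not hard word.
# Agents whose subjective hard-math cost exceeds a threshold switch to a
# fast-guessing policy (quick, chance-level answers) on hard math solves.

#' Construct a simulated participant
#'
#' Bundles trait scores with the generative parameters of the solve and
#' choice models. Defaults are calibrated so that an average agent scores
#' above 90\% on level-1 (easy) problems and equilibrates near the
#' 2-up-1-down target of ~70.7\% on staircased hard problems.
#'
#' @param math_anxiety,reading_anxiety Trait scores on 1-5 scales.
#' @param trait_anxiety,test_anxiety Composite scores on 20-80 scales.
#' @param competence_math,competence_word Psychometric locations: the
#'   latent difficulty at which raw (pre-floor) accuracy is 50\%.
#' @param psychometric_slope Steepness of the accuracy-vs-difficulty
#'   logistic (per latent-difficulty unit).
#' @param lapse Lapse rate in \[0, 0.1\]: accuracy ceiling is 1 - lapse.
#' @param cost_base_math,cost_base_word Effort cost per difficulty-level
#'   unit, in cents.
#' @param anxiety_cost_slope Extra math cost (cents per level unit) per
#'   math-anxiety unit above 1; the anxiety -> avoidance channel.
#' @param choice_temperature Softmax temperature (cents); lower = more
#'   deterministic value maximisation.
#' @param perceived_acc_easy,perceived_acc_hard The agent's beliefs about
#'   its accuracy, fixed at the design constants 0.95 / 0.70 by default.
#' @param guess_threshold Subjective hard cost (cents) above which the
#'   agent answers hard math by fast guessing.
#' @param timeout_prob Probability of letting the 3-s choose phase lapse.
#' @param rt_choose_meanlog,rt_choose_sdlog,rt_solve_meanlog,
#'   rt_solve_sdlog,rt_guess_meanlog,rt_guess_sdlog Log-normal RT
#'   parameters for the choose phase, normal solving, and guessing.
#' @param id Participant identifier.
#' @return An object of class \code{agent_params} (a list).
#' @export
agent_params <- function(math_anxiety = 2.5,
                         reading_anxiety = 2.0,
                         trait_anxiety = 40,
                         test_anxiety = 45,
                         competence_math = 4.3,
                         competence_word = 4.3,
                         psychometric_slope = 1.0,
                         lapse = 0.02,
                         cost_base_math = 0.1,
                         cost_base_word = 0.1,
                         anxiety_cost_slope = 0,
                         choice_temperature = 0.5,
                         perceived_acc_easy = 0.95,
                         perceived_acc_hard = 0.70,
                         guess_threshold = 5,
                         timeout_prob = 0.01,
                         rt_choose_meanlog = log(1.0),
                         rt_choose_sdlog = 0.3,
                         rt_solve_meanlog = log(3.5),
                         rt_solve_sdlog = 0.35,
                         rt_guess_meanlog = log(1.8),
                         rt_guess_sdlog = 0.2,
                         id = "agent-1") {
  a <- list(id = as.character(id),
            math_anxiety = math_anxiety, reading_anxiety = reading_anxiety,
            trait_anxiety = trait_anxiety, test_anxiety = test_anxiety,
            competence_math = competence_math,
            competence_word = competence_word,
            psychometric_slope = psychometric_slope, lapse = lapse,
            cost_base_math = cost_base_math, cost_base_word = cost_base_word,
            anxiety_cost_slope = anxiety_cost_slope,
            choice_temperature = choice_temperature,
            perceived_acc_easy = perceived_acc_easy,
            perceived_acc_hard = perceived_acc_hard,
            guess_threshold = guess_threshold, timeout_prob = timeout_prob,
            rt_choose_meanlog = rt_choose_meanlog,
            rt_choose_sdlog = rt_choose_sdlog,
            rt_solve_meanlog = rt_solve_meanlog,
            rt_solve_sdlog = rt_solve_sdlog,
            rt_guess_meanlog = rt_guess_meanlog,
            rt_guess_sdlog = rt_guess_sdlog)
  stopifnot(a$psychometric_slope > 0, a$choice_temperature > 0,
            a$lapse >= 0, a$lapse <= 0.1,
            a$perceived_acc_easy >= 0, a$perceived_acc_easy <= 1,
            a$perceived_acc_hard >= 0, a$perceived_acc_hard <= 1,
            a$cost_base_math >= 0, a$cost_base_word >= 0,
            a$timeout_prob >= 0, a$timeout_prob <= 1)
  class(a) <- "agent_params"
  a
}

#' Solving accuracy of an agent
#'
#' Probability of answering a three-alternative problem correctly:
#' \deqn{p = 1/3 + (2/3 - lapse) \cdot
#'   \sigma(slope \cdot (competence - difficulty))}
#' with floor 1/3 (pure guessing among three options) and ceiling
#' 1 - lapse. Decreasing in difficulty by construction.
#'
#' @param agent An \code{agent_params}.
#' @param domain \code{"math"} or \code{"word"} (selects the competence).
#' @param difficulty Latent difficulty; integer levels 1..7 can be passed
#'   directly (level and mean latent difficulty share the same scale).
#' @return Accuracy in \[1/3, 1 - lapse\]. Vectorised over
#'   \code{difficulty}.
#' @export
solve_accuracy <- function(agent, domain, difficulty) {
  comp <- if (domain == "math") agent$competence_math else
    agent$competence_word
  1 / 3 + (2 / 3 - agent$lapse) *
    stats::plogis(agent$psychometric_slope * (comp - difficulty))
}

# per-level-unit effort cost in cents; anxiety loads on math only
.cost_per_level <- function(agent, domain) {
  if (domain == "math") {
    agent$cost_base_math +
      agent$anxiety_cost_slope * (agent$math_anxiety - 1)
  } else {
    agent$cost_base_word
  }
}

# effort scales linearly with difficulty level
.effort_cost <- function(agent, domain, level) {
  .cost_per_level(agent, domain) * level
}

#' Subjective values of an offer
#'
#' SV(card) = believed accuracy x reward - effort cost at the level the
#' card implies: level 1 for easy, the current staircase level for hard.
#'
#' @param agent An \code{agent_params}.
#' @param domain Trial domain.
#' @param easy_reward,hard_reward Offered rewards in cents.
#' @param current_level Current hard-staircase level for the domain.
#' @return Named numeric vector \code{c(easy = , hard = )}, in cents.
#' @export
subjective_values <- function(agent, domain, easy_reward, hard_reward,
                              current_level) {
  c(easy = agent$perceived_acc_easy * easy_reward -
      .effort_cost(agent, domain, 1L),
    hard = agent$perceived_acc_hard * hard_reward -
      .effort_cost(agent, domain, current_level))
}

#' Probability that an agent picks the hard card
#'
#' Softmax (logistic) in the subjective-value difference:
#' \code{plogis((SV_hard - SV_easy) / temperature)}. Monotone increasing
#' in \code{hard_reward} for every agent.
#'
#' @inheritParams subjective_values
#' @return Probability in (0, 1).
#' @export
choice_prob_hard <- function(agent, domain, easy_reward, hard_reward,
                             current_level) {
  sv <- subjective_values(agent, domain, easy_reward, hard_reward,
                          current_level)
  stats::plogis((sv[["hard"]] - sv[["easy"]]) / agent$choice_temperature)
}

#' Sample one choose-phase decision
#'
#' Emits \code{"timeout"} with the agent's fixed lapse probability, else
#' \code{"hard"} with the softmax probability and \code{"easy"} otherwise.
#' Uses the current R random stream.
#'
#' @inheritParams subjective_values
#' @return One of \code{"easy"}, \code{"hard"}, \code{"timeout"}.
#' @export
choose_card <- function(agent, domain, easy_reward, hard_reward,
                        current_level) {
  if (stats::runif(1) < agent$timeout_prob) return("timeout")
  p_hard <- choice_prob_hard(agent, domain, easy_reward, hard_reward,
                             current_level)
  if (stats::runif(1) < p_hard) "hard" else "easy"
}

#' Is the agent in fast-guessing mode for this solve?
#'
#' A hard switch: when the subjective effort cost of the hard problem at
#' the current level exceeds \code{guess_threshold}, the agent answers
#' quickly at chance (1/3). Models the reported pattern of anxious
#' participants spending less time on hard math and scoring worse on it.
#'
#' @inheritParams subjective_values
#' @param level Level of the problem being solved.
#' @return Logical scalar.
#' @export
is_guessing <- function(agent, domain, level) {
  level > 1L && .effort_cost(agent, domain, level) > agent$guess_threshold
}

#' Sample a response time
#'
#' Log-normal durations. Choose-phase RTs are clipped to (0, 3\] s. For
#' the solve phase the raw draw is compared with the 7-s limit: a draw
#' beyond the limit is a solve timeout (return value \code{NA} with
#' attribute \code{timeout = TRUE}); otherwise the RT is clipped up to
#' the 1.5-s response lockout. Guessing mode uses a faster distribution.
#'
#' @param agent An \code{agent_params}.
#' @param phase \code{"choose"} or \code{"solve"}.
#' @param guessing Logical: fast-guessing mode (solve phase only).
#' @param choose_limit,solve_limit,lockout Timing constants in seconds.
#' @return Seconds, or \code{NA} with \code{attr(, "timeout") = TRUE} for
#'   a solve that ran out of time.
#' @export
sample_rt <- function(agent, phase = c("choose", "solve"), guessing = FALSE,
                      choose_limit = 3, solve_limit = 7, lockout = 1.5) {
  phase <- match.arg(phase)
  if (phase == "choose") {
    rt <- stats::rlnorm(1, agent$rt_choose_meanlog, agent$rt_choose_sdlog)
    return(min(rt, choose_limit))
  }
  if (guessing) {
    rt <- stats::rlnorm(1, agent$rt_guess_meanlog, agent$rt_guess_sdlog)
  } else {
    rt <- stats::rlnorm(1, agent$rt_solve_meanlog, agent$rt_solve_sdlog)
  }
  if (rt > solve_limit) {
    return(structure(NA_real_, timeout = TRUE))
  }
  max(rt, lockout)
}
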