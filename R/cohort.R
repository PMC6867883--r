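# Cohort synthesis and effect calibration.
#
# Traits are drawn from a latent multivariate normal (math anxiety,
# reading anxiety, trait anxiety, test anxiety) with a configurable
# correlation matrix, affine-mapped to their questionnaire scales and
# clipped. Math anxiety is positively correlated with the other three by
# default, which is the qualitative structure the analyses assume.
# Agents inherit psychometric and cost parameters from their traits; the
# anxiety -> math-effort-cost slope is the single knob that creates a
# negative math-HCP effect, and calibrate_effect() finds the slope that
# yields a requested population correlation.

.TRAITS <- c("math_anxiety", "reading_anxiety", "trait_anxiety",
             "test_anxiety")

.default_trait_corr <- function() {
  m <- matrix(c(
    1.00, 0.30, 0.35, 0.50,
    0.30, 1.00, 0.25, 0.30,
    0.35, 0.25, 1.00, 0.60,
    0.50, 0.30, 0.60, 1.00), 4, 4,
    dimnames = list(.TRAITS, .TRAITS))
  m
}

#' Cohort configuration
#'
#' @param n Number of agents.
#' @param trait_means,trait_sds Named numeric vectors over the four
#'   traits (math/reading anxiety on 1-5, trait/test anxiety on 20-80).
#' @param trait_corr 4x4 positive semi-definite correlation matrix.
#' @param anxiety_cost_slope Math effort-cost slope per anxiety unit
#'   (cents per difficulty level). Mutually exclusive with
#'   \code{target_r}.
#' @param target_r Desired population correlation between math anxiety
#'   and math HCP; resolved to a slope by \code{\link{calibrate_effect}}.
#' @param seed Integer seed.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n,
                          trait_means = c(math_anxiety = 2.2,
                                          reading_anxiety = 1.8,
                                          trait_anxiety = 40,
                                          test_anxiety = 42),
                          trait_sds = c(math_anxiety = 0.8,
                                        reading_anxiety = 0.6,
                                        trait_anxiety = 10,
                                        test_anxiety = 11),
                          trait_corr = .default_trait_corr(),
                          anxiety_cost_slope = NULL,
                          target_r = NULL,
                          seed = 1) {
  if (!is.null(anxiety_cost_slope) && !is.null(target_r)) {
    stop("set exactly one of anxiety_cost_slope and target_r",
         call. = FALSE)
  }
  stopifnot(n >= 0, all(.TRAITS %in% names(trait_means)),
            all(.TRAITS %in% names(trait_sds)))
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("trait correlation matrix is not positive semi-definite",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), trait_means = trait_means,
                 trait_sds = trait_sds, trait_corr = trait_corr,
                 anxiety_cost_slope = anxiety_cost_slope,
                 target_r = target_r, seed = as.integer(seed)),
            class = "cohort_config")
}

# scale bounds per trait
.trait_bounds <- list(math_anxiety = c(1, 5), reading_anxiety = c(1, 5),
                      trait_anxiety = c(20, 80), test_anxiety = c(20, 80))

#' Draw correlated trait profiles
#'
#' Latent multivariate normal, affine-mapped to each questionnaire scale,
#' then clipped to the scale bounds. Demographic strata (age band,
#' gender) are uniform categorical draws used only as regression
#' covariates.
#'
#' @param config A \code{cohort_config}.
#' @return data.frame with one row per profile: \code{participant_id},
#'   the four trait scores, \code{age_band}, \code{gender}.
#' @export
generate_traits <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  set.seed(config$seed)
  if (n == 0L) {
    return(data.frame(participant_id = character(0)))
  }
  L <- chol(config$trait_corr + diag(1e-10, 4))
  z <- matrix(stats::rnorm(n * 4L), n, 4L) %*% L
  colnames(z) <- .TRAITS
  out <- data.frame(participant_id = sprintf("p%04d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (tr in .TRAITS) {
    v <- config$trait_means[[tr]] + config$trait_sds[[tr]] * z[, tr]
    b <- .trait_bounds[[tr]]
    out[[tr]] <- pmin(pmax(v, b[1]), b[2])
  }
  out$age_band <- sample(c("18-25", "26-35", "36-45", "46+"), n,
                         replace = TRUE)
  out$gender <- sample(c("female", "male", "other"), n, replace = TRUE,
                       prob = c(0.48, 0.48, 0.04))
  out
}

#' Default trait-to-agent calibration
#'
#' The mapping from trait profiles to generative agent parameters:
#' competences are normal around \code{competence_mean}, math competence
#' optionally coupled (negatively) to math anxiety so that anxious agents
#' equilibrate at lower staircase levels (the ADL link); per-domain base
#' effort costs get independent agent-level noise so anxiety is not the
#' only source of choice heterogeneity.
#'
#' @param anxiety_cost_slope Cents of extra math cost per level unit per
#'   math-anxiety unit above 1.
#' @param competence_mean,competence_sd Competence distribution.
#' @param competence_anxiety_coupling Change in math competence per
#'   math-anxiety unit (default -0.15).
#' @param cost_base_mean,cost_base_sd Agent-level base-cost distribution
#'   (truncated at 0).
#' @param guess_threshold Subjective-cost switch for fast guessing;
#'   \code{Inf} (default) disables guessing.
#' @param ... Overrides passed straight to \code{\link{agent_params}}
#'   (e.g. \code{choice_temperature}).
#' @return A calibration list for \code{\link{traits_to_agents}}.
#' @export
default_calibration <- function(anxiety_cost_slope = 0,
                                competence_mean = 4.3,
                                competence_sd = 0.5,
                                competence_anxiety_coupling = -0.15,
                                cost_base_mean = 0.1,
                                cost_base_sd = 0.15,
                                guess_threshold = Inf,
                                ...) {
  list(anxiety_cost_slope = anxiety_cost_slope,
       competence_mean = competence_mean,
       competence_sd = competence_sd,
       competence_anxiety_coupling = competence_anxiety_coupling,
       cost_base_mean = cost_base_mean,
       cost_base_sd = cost_base_sd,
       guess_threshold = guess_threshold,
       extra = list(...))
}

#' Map trait profiles to agents
#'
#' One agent per profile, deterministic given \code{seed}.
#'
#' @param profiles data.frame from \code{\link{generate_traits}}.
#' @param calibration List from \code{\link{default_calibration}}.
#' @param seed Integer seed for the agent-level parameter noise.
#' @return List of \code{agent_params}.
#' @export
traits_to_agents <- function(profiles, calibration = default_calibration(),
                             seed = 1) {
  n <- nrow(profiles)
  set.seed(as.integer(seed))
  cal <- calibration
  anx_center <- 2.2   # coupling is centred so the mean agent is unchanged
  comp_math <- cal$competence_mean +
    cal$competence_anxiety_coupling * (profiles$math_anxiety - anx_center) +
    stats::rnorm(n, 0, cal$competence_sd)
  comp_word <- cal$competence_mean + stats::rnorm(n, 0, cal$competence_sd)
  cb_math <- pmax(stats::rnorm(n, cal$cost_base_mean, cal$cost_base_sd), 0)
  cb_word <- pmax(stats::rnorm(n, cal$cost_base_mean, cal$cost_base_sd), 0)
  agents <- vector("list", n)
  for (j in seq_len(n)) {
    args <- c(list(
      id = profiles$participant_id[j],
      math_anxiety = profiles$math_anxiety[j],
      reading_anxiety = profiles$reading_anxiety[j],
      trait_anxiety = profiles$trait_anxiety[j],
      test_anxiety = profiles$test_anxiety[j],
      competence_math = comp_math[j],
      competence_word = comp_word[j],
      cost_base_math = cb_math[j],
      cost_base_word = cb_word[j],
      anxiety_cost_slope = cal$anxiety_cost_slope,
      guess_threshold = cal$guess_threshold), cal$extra)
    agents[[j]] <- do.call(agent_params, args)
  }
  agents
}

# --- analytic expected HCP -------------------------------------------------
#
# The staircase holds an agent near the level where its accuracy equals
# sqrt(0.5); treating that (continuous) equilibrium level as the level the
# agent faces on every choice gives a closed-form expected HCP, and adding
# the binomial measurement variance implied by the design's trial counts
# gives the expected *observed* anxiety-HCP correlation without simulating.

#' Staircase equilibrium level of an agent
#'
#' Continuous level at which \code{\link{solve_accuracy}} equals the
#' 2-up-1-down convergence accuracy, clipped to the staircase bounds.
#'
#' @param agent An \code{agent_params}.
#' @param domain \code{"math"} or \code{"word"}.
#' @return Level in \[2, 7\].
#' @export
equilibrium_level <- function(agent, domain) {
  p_star <- convergence_accuracy("2up1down")
  q <- (p_star - 1 / 3) / (2 / 3 - agent$lapse)
  comp <- if (domain == "math") agent$competence_math else
    agent$competence_word
  lv <- comp - stats::qlogis(q) / agent$psychometric_slope
  min(max(lv, 2), 7)
}

#' Expected HCP of one agent (closed form)
#'
#' Mean over the 4/5/6-cent conditions of the softmax hard-choice
#' probability with the hard card evaluated at the agent's staircase
#' equilibrium level.
#'
#' @inheritParams equilibrium_level
#' @param design A \code{session_design} (for the reward constants).
#' @return Expected HCP in (0, 1).
#' @export
expected_hcp <- function(agent, domain, design = build_design("study1")) {
  lv <- equilibrium_level(agent, domain)
  mean(vapply(4:6, function(r) {
    choice_prob_hard(agent, domain, design$easy_reward, r, lv)
  }, numeric(1)))
}

# expected observed correlation between math anxiety and math HCP,
# including the binomial measurement noise from finite trial counts
.expected_observed_r <- function(agents, design, domain = "math") {
  anx <- vapply(agents, `[[`, numeric(1), "math_anxiety")
  hcp <- numeric(length(agents))
  noise <- numeric(length(agents))
  m_per_cond <- design$blocks * design$choice_per_domain / 5
  for (j in seq_along(agents)) {
    a <- agents[[j]]
    lv <- equilibrium_level(a, domain)
    p <- vapply(4:6, function(r) {
      choice_prob_hard(a, domain, design$easy_reward, r, lv)
    }, numeric(1))
    hcp[j] <- mean(p)
    m_eff <- m_per_cond * (1 - a$timeout_prob)
    noise[j] <- sum(p * (1 - p) / m_eff) / 9
  }
  num <- stats::cov(anx, hcp)
  den <- sqrt(stats::var(anx) * (stats::var(hcp) + mean(noise)))
  num / den
}

#' Calibrate the anxiety-to-cost slope to a target correlation
#'
#' Finds, by monotone bisection, the math effort-cost slope per anxiety
#' unit such that a large synthetic cohort run through \code{design}
#' shows the requested correlation between math anxiety and math HCP.
#' The objective is the closed-form expected observed correlation
#' (equilibrium-level HCP plus binomial measurement noise at the
#' design's per-condition trial counts), evaluated on \code{n_calib}
#' trait draws, so calibration is fast and deterministic.
#'
#' @param target_r Target correlation in (-1, 0\].
#' @param design A \code{session_design}.
#' @param base_config A \code{cohort_config} providing the trait world;
#'   its \code{n} is overridden by \code{n_calib}.
#' @param calibration Baseline calibration (slope is overwritten).
#' @param n_calib Trait draws used for the objective (default 2000).
#' @param tol Bisection tolerance on the correlation.
#' @param refine Polish the analytic solution with full-session
#'   simulation (default \code{TRUE}): the closed form ignores staircase
#'   transients (agents who rarely choose hard stay near the level-4
#'   start rather than their equilibrium), which biases the achieved
#'   correlation by a few hundredths; one Newton step against a simulated
#'   cohort of \code{n_sim} agents removes it.
#' @param n_sim Cohort size for the refinement simulations.
#' @return The slope, with attribute \code{report}: a list with
#'   \code{target_r}, \code{achieved_r} (simulated when \code{refine},
#'   else analytic), \code{slope}, \code{iterations}.
#' @export
calibrate_effect <- function(target_r, design, base_config,
                             calibration = default_calibration(),
                             n_calib = 2000L, tol = 0.005,
                             refine = TRUE, n_sim = 1500L) {
  if (!(target_r <= 0 && target_r > -1)) {
    stop("target_r must lie in (-1, 0]", call. = FALSE)
  }
  cfg <- base_config
  cfg$n <- as.integer(n_calib)
  profiles <- generate_traits(cfg)

  r_at <- function(slope) {
    cal <- calibration
    cal$anxiety_cost_slope <- slope
    agents <- traits_to_agents(profiles, cal, seed = cfg$seed + 1L)
    .expected_observed_r(agents, design)
  }

  if (target_r == 0) {
    out <- 0
    attr(out, "report") <- list(target_r = 0, achieved_r = r_at(0),
                                slope = 0, iterations = 0L)
    return(out)
  }

  lo <- 0; r_lo <- r_at(lo)
  hi <- 1; r_hi <- r_at(hi)
  it <- 0L
  while (r_hi > target_r && hi < 64) {   # expand until the target is bracketed
    hi <- hi * 2; r_hi <- r_at(hi); it <- it + 1L
  }
  if (r_hi > target_r) {
    stop(sprintf(
      "target_r = %.3f unattainable: achievable range is [%.3f, %.3f]",
      target_r, r_hi, r_lo), call. = FALSE)
  }
  for (k in 1:40) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    r_mid <- r_at(mid)
    if (abs(r_mid - target_r) < tol) {
      lo <- hi <- mid
      break
    }
    if (r_mid > target_r) lo <- mid else hi <- mid
  }
  slope <- (lo + hi) / 2
  achieved <- r_at(slope)

  if (refine) {
    sim_r <- function(s) {
      cal <- calibration
      cal$anxiety_cost_slope <- s
      cfg_s <- base_config
      cfg_s$n <- as.integer(n_sim)
      agents <- traits_to_agents(generate_traits(cfg_s), cal,
                                 seed = cfg$seed + 2L)
      log <- run_cohort(agents, design,
                        bank = generate_bank(700, 700, seed = cfg$seed + 3L),
                        seed = cfg$seed + 4L, include_practice = FALSE)
      s_tab <- summarize_participants(log)
      anx <- vapply(agents, `[[`, numeric(1), "math_anxiety")
      stats::cor(anx, s_tab$math_hcp, use = "complete.obs")
    }
    r0 <- sim_r(slope)
    # analytic derivative dr/dslope for the Newton step
    ds <- max(0.02, 0.1 * slope)
    deriv <- (r_at(slope + ds) - r_at(max(slope - ds, 0))) /
      (slope + ds - max(slope - ds, 0))
    slope1 <- max(slope + (target_r - r0) / deriv, 0)
    r1 <- sim_r(slope1)
    it <- it + 2L
    if (abs(r1 - target_r) <= abs(r0 - target_r)) {
      slope <- slope1; achieved <- r1
    } else {
      achieved <- r0
    }
  }

  out <- slope
  attr(out, "report") <- list(target_r = target_r, achieved_r = achieved,
                              slope = slope, iterations = it)
  out
}
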