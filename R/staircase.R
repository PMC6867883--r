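# 2-up-1-down adaptive staircase controlling hard-problem difficulty.
#
# The rule: difficulty goes up one level after two consecutive correct
# answers, down one level after a single error, and is clamped to [2, 7].
# Its equilibrium is the accuracy p* solving p*^2 = 1/2, i.e. sqrt(0.5)
# ~ 70.7% correct, which is why hard-problem accuracy clusters near 70%
# whatever the participant's competence.

#' Initialise a 2-up-1-down staircase
#'
#' Creates the difficulty-tracking state used for hard problems in one
#' domain. The staircase starts at level 4 and moves within \[2, 7\]:
#' up one level after two successive correct answers, down one level
#' after any error.
#'
#' @param level Starting difficulty level (default 4).
#' @param min_level,max_level Level bounds (defaults 2 and 7).
#' @return An object of class \code{staircase_state}: a list with fields
#'   \code{level}, \code{streak} (consecutive correct answers since the
#'   last level change or error, 0 or 1), \code{min_level},
#'   \code{max_level}, and \code{history} (two-column matrix of
#'   \code{level}, \code{correct} pairs, one row per update).
#' @examples
#' st <- init_staircase()
#' st$level   # 4
#' @export
init_staircase <- function(level = 4L, min_level = 2L, max_level = 7L) {
  level <- as.integer(level)
  min_level <- as.integer(min_level)
  max_level <- as.integer(max_level)
  if (min_level > max_level) {
    stop("min_level must not exceed max_level", call. = FALSE)
  }
  if (level < min_level || level > max_level) {
    stop("starting level must lie within [min_level, max_level]",
         call. = FALSE)
  }
  structure(
    list(level = level, streak = 0L,
         min_level = min_level, max_level = max_level,
         history = matrix(integer(0), ncol = 2L,
                          dimnames = list(NULL, c("level", "correct")))),
    class = "staircase_state"
  )
}

#' Advance a staircase by one hard-solve outcome
#'
#' Applies the 2-up-1-down rule. A correct answer on a streak of one
#' raises the level (clamped at \code{max_level}) and resets the streak;
#' a correct answer on a fresh streak just arms the streak; any error
#' lowers the level (clamped at \code{min_level}) and resets the streak.
#' The level/outcome pair is appended to \code{history}.
#'
#' @param state A \code{staircase_state}.
#' @param correct Logical scalar: was the hard solve correct? A solve
#'   timeout counts as incorrect.
#' @return The updated \code{staircase_state}.
#' @examples
#' st <- init_staircase()
#' st <- staircase_update(st, TRUE)
#' st <- staircase_update(st, TRUE)  # second success: level 4 -> 5
#' st$level
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"),
            is.logical(correct), length(correct) == 1L, !is.na(correct))
  lvl <- state$level
  state$history <- rbind(state$history,
                         c(level = lvl, correct = as.integer(correct)))
  if (correct) {
    if (state$streak >= 1L) {
      state$level <- min(lvl + 1L, state$max_level)
      state$streak <- 0L
    } else {
      state$streak <- 1L
    }
  } else {
    state$level <- max(lvl - 1L, state$min_level)
    state$streak <- 0L
  }
  state
}

#' Theoretical convergence accuracy of a staircase rule
#'
#' For an n-up-1-down staircase the equilibrium accuracy p solves
#' p^n = 1/2 (the level is equally likely to step up as down), so the
#' 2-up-1-down rule used for hard problems converges to
#' sqrt(0.5) = 0.7071..., the usual "70% target".
#'
#' @param rule Character, one of \code{"2up1down"} or \code{"1up1down"}.
#' @return The asymptotic proportion correct at equilibrium.
#' @examples
#' convergence_accuracy("2up1down")  # 0.7071068
#' @export
convergence_accuracy <- function(rule = "2up1down") {
  n_up <- switch(rule,
                 "1up1down" = 1,
                 "2up1down" = 2,
                 stop("staircase rule not implemented: ", rule,
                      call. = FALSE))
  0.5^(1 / n_up)
}
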