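# Synthetic problem banks.
#
# Real item pools were sorted into seven difficulty levels by a validation
# study; here each item carries a latent difficulty drawn from a
# level-indexed distribution, so only the ordering (which is all the agent
# psychometric model consumes) is reproduced. Word items stay abstract:
# a latent difficulty with no rendered surface form.

# near-uniform allocation of n items over levels 1..7, remainder to the
# lower levels
.allocate_levels <- function(n, n_levels = 7L) {
  base <- n %/% n_levels
  rem <- n %% n_levels
  counts <- rep(base, n_levels)
  if (rem > 0L) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  counts
}

#' Generate a synthetic problem bank
#'
#' Builds a pool of math and word items spread near-uniformly over seven
#' difficulty levels (any remainder goes to the lower levels). Each item
#' gets a latent difficulty drawn from a normal distribution centred on
#' its level, so mean latent difficulty is strictly increasing in level.
#'
#' @param n_math,n_word Item counts per domain (non-negative).
#' @param seed Integer seed; identical seeds give identical banks.
#' @param latent_sd Spread of latent difficulty within a level.
#' @return An object of class \code{problem_bank}: list with
#'   \code{problems} (data.frame with columns \code{id}, \code{domain},
#'   \code{level}, \code{latent_difficulty}) and a private draw-state
#'   environment used by \code{\link{draw_problem}}.
#' @examples
#' bank <- generate_bank(70, 70, seed = 1)
#' table(bank$problems$domain, bank$problems$level)
#' @export
generate_bank <- function(n_math, n_word, seed, latent_sd = 0.15) {
  if (n_math < 0 || n_word < 0) {
    stop("item counts must be non-negative", call. = FALSE)
  }
  n_math <- as.integer(n_math)
  n_word <- as.integer(n_word)
  set.seed(as.integer(seed))
  rows <- list()
  for (dom in c("math", "word")) {
    n <- if (dom == "math") n_math else n_word
    if (n == 0L) next
    counts <- .allocate_levels(n)
    lev <- rep(seq_len(7L), counts)
    rows[[dom]] <- data.frame(
      id = sprintf("%s-%05d", dom, seq_len(n)),
      domain = dom,
      level = lev,
      latent_difficulty = stats::rnorm(n, mean = lev, sd = latent_sd),
      stringsAsFactors = FALSE
    )
  }
  problems <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), domain = character(0),
               level = integer(0), latent_difficulty = numeric(0),
               stringsAsFactors = FALSE)
  rownames(problems) <- NULL
  structure(list(problems = problems, .draws = new.env(parent = emptyenv())),
            class = "problem_bank")
}

#' @export
print.problem_bank <- function(x, ...) {
  tab <- table(x$problems$domain, x$problems$level)
  cat("<problem_bank> ", nrow(x$problems), " items\n", sep = "")
  if (nrow(x$problems)) print(tab)
  invisible(x)
}

# row indices of one (domain, level) cell
.bank_cell <- function(bank, domain, level) {
  which(bank$problems$domain == domain & bank$problems$level == level)
}

#' Reset the without-replacement draw state of a bank
#'
#' Draws from a cell are without replacement until the cell is exhausted,
#' at which point it silently resets. Call this at session boundaries so
#' each simulated session starts from a full pool.
#'
#' @param bank A \code{problem_bank}.
#' @return The bank, invisibly.
#' @export
reset_bank_draws <- function(bank) {
  stopifnot(inherits(bank, "problem_bank"))
  rm(list = ls(bank$.draws), envir = bank$.draws)
  invisible(bank)
}

#' Draw one problem from a bank cell
#'
#' Samples an item of the requested domain and level, without replacement
#' within the current draw cycle; once every item of the cell has been
#' served the cell resets, so repeats are possible but maximally delayed.
#' Uses the current R random stream.
#'
#' @param bank A \code{problem_bank}.
#' @param domain \code{"math"} or \code{"word"}.
#' @param level Integer level 1..7.
#' @return One-row data.frame (a \code{ProblemSpec}).
#' @export
draw_problem <- function(bank, domain, level) {
  stopifnot(inherits(bank, "problem_bank"))
  domain <- match.arg(domain, c("math", "word"))
  level <- as.integer(level)
  cell <- .bank_cell(bank, domain, level)
  if (!length(cell)) {
    stop(sprintf("problem bank cell (%s, level %d) is empty", domain, level),
         call. = FALSE)
  }
  key <- paste0(domain, ".", level)
  used <- if (exists(key, envir = bank$.draws)) get(key, envir = bank$.draws)
          else integer(0)
  avail <- setdiff(cell, used)
  if (!length(avail)) {      # cycle exhausted: reset the cell
    used <- integer(0)
    avail <- cell
  }
  pick <- if (length(avail) == 1L) avail else
    avail[sample.int(length(avail), 1L)]
  assign(key, c(used, pick), envir = bank$.draws)
  bank$problems[pick, , drop = FALSE]
}

#' Render a missing-digit multiplication item
#'
#' Produces a concrete math item in the task's format: a multi-digit
#' multiplication with exactly one digit of the product blanked out and a
#' bank of three candidate digits, exactly one correct. Operand size grows
#' with level (the documented heuristic: the two operands together carry
#' \code{level + 2} digits), which is what makes higher levels harder.
#'
#' @param level Integer level 1..7.
#' @return List with \code{statement} (e.g. \code{"44 x 7 = 30_"} with
#'   \code{_} the blank), \code{options} (three digit characters),
#'   \code{answer_index} (position of the correct option), and
#'   \code{answer} (the correct digit).
#' @examples
#' set.seed(1); render_math_item(3)
#' @export
render_math_item <- function(level) {
  level <- as.integer(level)
  if (is.na(level) || level < 1L || level > 7L) {
    stop("level must be an integer in [1, 7]", call. = FALSE)
  }
  d1 <- 1L + ceiling(level / 2)   # digits in first operand
  d2 <- 1L + level %/% 2          # digits in second operand
  rand_int <- function(digits) {
    lo <- if (digits == 1L) 2L else as.integer(10^(digits - 1L))
    hi <- as.integer(10^digits - 1L)
    lo + sample.int(hi - lo + 1L, 1L) - 1L
  }
  a <- rand_int(d1)
  b <- rand_int(d2)
  prod_chars <- strsplit(as.character(a * b), "")[[1]]
  blank <- sample.int(length(prod_chars), 1L)
  answer <- prod_chars[blank]
  shown <- prod_chars
  shown[blank] <- "_"
  distractors <- sample(setdiff(as.character(0:9), answer), 2L)
  options <- sample(c(answer, distractors))
  list(
    statement = sprintf("%d x %d = %s", a, b, paste(shown, collapse = "")),
    options = options,
    answer_index = match(answer, options),
    answer = answer
  )
}
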