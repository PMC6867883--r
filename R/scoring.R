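# Scoring: reduce trial logs to per-participant measures.
#
# HCP (hard choice probability): the hard card is financially worth
# choosing whenever it offers more than 3 cents (0.70 x 4 = 2.8 beats
# 0.95 x 2 = 1.9), so the canonical index merges the 4-, 5-, and 6-cent
# conditions and averages the three per-condition hard-choice proportions.
# ADL (average difficulty level): mean staircase level over all hard
# problems encountered, a competence proxy.
#
# Conventions (documented, applied consistently): practice trials never
# score; choice-timeout trials are excluded from HCP and from accuracy
# denominators; solve timeouts count as incorrect answers; RT summaries
# use answered trials only; no-choice trials feed accuracy/RT/ADL but not
# HCP.

# scoreable (non-practice) rows of one participant + domain
.dom_rows <- function(records, domain) {
  records[!records$is_practice & records$domain == domain, , drop = FALSE]
}

#' Expected value of a choice card
#'
#' Offered reward times the probability of solving correctly; e.g. a
#' 4-cent hard card at 70\% accuracy is worth 4 x 0.7 = 2.8 cents, while
#' the easy card is worth 2 x 0.95 = 1.9 cents.
#'
#' @param reward Reward in cents (>= 0).
#' @param accuracy Success probability in \[0, 1\].
#' @return Expected value in cents. Vectorised.
#' @examples
#' expected_value(4, 0.7)   # 2.8
#' @export
expected_value <- function(reward, accuracy) {
  stopifnot(all(reward >= 0), all(accuracy >= 0), all(accuracy <= 1))
  reward * accuracy
}

#' Hard choice probability
#'
#' Proportion of hard-card choices on free-choice trials where the hard
#' card offered 4, 5, or 6 cents. The canonical form averages the three
#' per-condition proportions (they coincide with the pooled proportion
#' under a balanced schedule). Practice, no-choice, and choice-timeout
#' trials are excluded.
#'
#' @param records Trial-log rows of one participant.
#' @param domain \code{"math"} or \code{"word"}.
#' @param method \code{"conditions"} (mean of the three per-condition
#'   proportions; canonical) or \code{"pooled"}.
#' @return Proportion in \[0, 1\].
#' @export
compute_hcp <- function(records, domain, method = c("conditions", "pooled")) {
  method <- match.arg(method)
  d <- .dom_rows(records, domain)
  d <- d[!d$is_no_choice & d$choice != "timeout" &
           !is.na(d$hard_reward_offered) &
           d$hard_reward_offered %in% 4:6, , drop = FALSE]
  props <- vapply(4:6, function(r) {
    cell <- d[d$hard_reward_offered == r, , drop = FALSE]
    if (!nrow(cell)) {
      stop(sprintf("HCP undefined: no valid %s trials in the %d-cent cell",
                   domain, r), call. = FALSE)
    }
    mean(cell$choice == "hard")
  }, numeric(1))
  if (method == "conditions") mean(props) else mean(d$choice == "hard")
}

#' Average difficulty level
#'
#' Mean staircase level over all hard problems encountered (chosen-hard
#' and forced-hard alike), practice excluded.
#'
#' @inheritParams compute_hcp
#' @return Mean level in \[2, 7\].
#' @export
compute_adl <- function(records, domain) {
  d <- .dom_rows(records, domain)
  hard <- d[d$choice == "hard", , drop = FALSE]
  if (!nrow(hard)) {
    stop(sprintf("ADL undefined: no hard %s trials", domain), call. = FALSE)
  }
  mean(hard$difficulty_level)
}

#' Proportion of hard solves that timed out
#'
#' @inheritParams compute_hcp
#' @return Proportion in \[0, 1\].
#' @export
timeout_proportion <- function(records, domain) {
  d <- .dom_rows(records, domain)
  hard <- d[d$choice == "hard", , drop = FALSE]
  if (!nrow(hard)) {
    stop(sprintf("no hard %s trials", domain), call. = FALSE)
  }
  mean(hard$solve_timeout)
}

#' Summarise a trial log per participant
#'
#' Computes the derived measures for every participant in a (possibly
#' multi-participant) log: HCP and ADL per domain, easy/hard accuracy and
#' mean RT per domain, hard-timeout proportions, and the exclusion flag
#' (easy accuracy below 70\% in either domain). Measures whose defining
#' cells are empty come back \code{NA} rather than erroring.
#'
#' @param records Trial-log data.frame.
#' @return data.frame, one row per participant.
#' @export
summarize_participants <- function(records) {
  ids <- unique(records$participant_id)
  by_id <- split(records, records$participant_id)[ids]
  out <- vector("list", length(ids))
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  for (j in seq_along(ids)) {
    rec <- by_id[[j]]
    row <- list(participant_id = ids[j])
    for (dom in c("math", "word")) {
      d <- .dom_rows(rec, dom)
      answered <- d[!is.na(d$solve_rt), , drop = FALSE]
      easy <- d[d$choice == "easy", , drop = FALSE]
      hard <- d[d$choice == "hard", , drop = FALSE]
      row[[paste0(dom, "_hcp")]] <- safe(compute_hcp(rec, dom))
      row[[paste0(dom, "_adl")]] <- safe(compute_adl(rec, dom))
      row[[paste0(dom, "_easy_accuracy")]] <-
        if (nrow(easy)) mean(easy$solve_correct) else NA_real_
      row[[paste0(dom, "_hard_accuracy")]] <-
        if (nrow(hard)) mean(hard$solve_correct) else NA_real_
      row[[paste0(dom, "_easy_rt")]] <- {
        e <- answered[answered$choice == "easy", , drop = FALSE]
        if (nrow(e)) mean(e$solve_rt) else NA_real_
      }
      row[[paste0(dom, "_hard_rt")]] <- {
        h <- answered[answered$choice == "hard", , drop = FALSE]
        if (nrow(h)) mean(h$solve_rt) else NA_real_
      }
      row[[paste0(dom, "_hard_timeout")]] <-
        if (nrow(hard)) mean(hard$solve_timeout) else NA_real_
    }
    row$excluded <- isTRUE(row$math_easy_accuracy < 0.70) ||
      isTRUE(row$word_easy_accuracy < 0.70) ||
      is.na(row$math_easy_accuracy) || is.na(row$word_easy_accuracy)
    out[[j]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the accuracy-based exclusion rule
#'
#' A participant is excluded when easy-problem accuracy is below 70\% in
#' either domain (strict \code{<}); an undefined easy accuracy also
#' excludes, with a warning. The returned partition is exhaustive and
#' disjoint.
#'
#' @param summaries data.frame from \code{\link{summarize_participants}}
#'   (needs \code{math_easy_accuracy}, \code{word_easy_accuracy}).
#' @return List with data.frames \code{kept} and \code{excluded}.
#' @export
apply_exclusions <- function(summaries) {
  ea_m <- summaries$math_easy_accuracy
  ea_w <- summaries$word_easy_accuracy
  undefined <- is.na(ea_m) | is.na(ea_w)
  if (any(undefined)) {
    warning(sum(undefined),
            " participant(s) with undefined easy accuracy treated as excluded")
  }
  drop <- undefined | ea_m < 0.70 | ea_w < 0.70
  drop[is.na(drop)] <- TRUE
  list(kept = summaries[!drop, , drop = FALSE],
       excluded = summaries[drop, , drop = FALSE])
}

#' Per-block measures
#'
#' HCP and ADL per participant per main block, for temporal-stability
#' (fatigue) checks.
#'
#' @param records Trial-log data.frame.
#' @return data.frame with columns \code{participant_id}, \code{block},
#'   \code{math_hcp}, \code{word_hcp}, \code{math_adl}, \code{word_adl}
#'   (\code{NA} where undefined within a block).
#' @export
block_measures <- function(records) {
  rec <- records[!records$is_practice, , drop = FALSE]
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  pieces <- split(rec, list(rec$participant_id, rec$block_index),
                  drop = TRUE)
  rows <- lapply(pieces, function(sub) {
    data.frame(participant_id = sub$participant_id[1],
               block = sub$block_index[1],
               math_hcp = safe(compute_hcp(sub, "math")),
               word_hcp = safe(compute_hcp(sub, "word")),
               math_adl = safe(compute_adl(sub, "math")),
               word_adl = safe(compute_adl(sub, "word")),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$participant_id, res$block), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-participant block slopes with a cohort sign test
#'
#' Ordinary least-squares slope of each measure against block index,
#' per participant, plus the cohort mean slope and a two-sided sign test
#' (fatigue would show as negative slopes).
#'
#' @param blocks data.frame from \code{\link{block_measures}}.
#' @param measures Which measure columns to analyse.
#' @return List with \code{slopes} (participant x measure data.frame) and
#'   \code{cohort} (measure, mean slope, sign-test p).
#' @export
block_slopes <- function(blocks,
                         measures = c("math_hcp", "word_hcp",
                                      "math_adl", "word_adl")) {
  ids <- unique(blocks$participant_id)
  slope1 <- function(y, x) {
    ok <- !is.na(y)
    if (sum(ok) < 2L) return(NA_real_)
    stats::cov(x[ok], y[ok]) / stats::var(x[ok])
  }
  sl <- lapply(ids, function(id) {
    sub <- blocks[blocks$participant_id == id, , drop = FALSE]
    if (length(unique(sub$block)) < 2L) {
      stop("block_slopes needs at least 2 blocks", call. = FALSE)
    }
    vals <- vapply(measures, function(m) slope1(sub[[m]], sub$block),
                   numeric(1))
    as.data.frame(c(list(participant_id = id), as.list(vals)),
                  stringsAsFactors = FALSE)
  })
  slopes <- do.call(rbind, sl)
  cohort <- do.call(rbind, lapply(measures, function(m) {
    v <- slopes[[m]]
    v <- v[!is.na(v)]
    nz <- v[v != 0]
    p <- if (length(nz)) stats::binom.test(sum(nz > 0), length(nz))$p.value
      else NA_real_
    data.frame(measure = m, mean_slope = mean(v), sign_test_p = p,
               stringsAsFactors = FALSE)
  }))
  list(slopes = slopes, cohort = cohort)
}
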