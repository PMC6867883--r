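# CSV dialects and bundled fixtures.
#
# All tabular artifacts are plain CSV with a versioned comment header
# ("#castsim-<kind>-v1") so files self-identify; JSON sidecars carry
# provenance (design, seed, agent). Money is integer cents; times are
# seconds with 3 decimals.

.LOG_COLUMNS <- c("participant_id", "study", "block_index", "trial_index",
                  "is_practice", "domain", "is_no_choice",
                  "hard_reward_offered", "choice", "choice_rt",
                  "difficulty_level", "problem_id", "solve_correct",
                  "solve_rt", "solve_timeout", "reward_earned")

.write_versioned_csv <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#castsim-%s-v1", kind), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_versioned_csv <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#")) 1L else 0L
  utils::read.csv(path, skip = skip, stringsAsFactors = FALSE)
}

#' Write / read a trial log
#'
#' Lossless round-trip of the trial-record table. \code{read_trial_log}
#' validates that every mandatory column is present (naming the missing
#' one otherwise) and preserves unknown extra columns.
#'
#' @param records Trial-log data.frame (see \code{\link{run_session}}).
#' @param path File path.
#' @return \code{write_trial_log}: the path, invisibly;
#'   \code{read_trial_log}: the trial-log data.frame.
#' @export
write_trial_log <- function(records, path) {
  missing <- setdiff(.LOG_COLUMNS, names(records))
  if (length(missing)) {
    stop("trial log lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  .write_versioned_csv(records, path, "log")
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  df <- .read_versioned_csv(path)
  missing <- setdiff(.LOG_COLUMNS, names(df))
  if (length(missing)) {
    stop("trial log schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("is_practice", "is_no_choice", "solve_correct",
                "solve_timeout")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Write a session provenance sidecar
#'
#' JSON record of the design, seed, and agent behind a log file.
#'
#' @param path Output path (conventionally \code{<log>.json}).
#' @param design A \code{session_design}.
#' @param seed Integer seed used for the session.
#' @param agent_id Participant identifier.
#' @return The path, invisibly.
#' @export
write_session_sidecar <- function(path, design, seed, agent_id) {
  payload <- list(
    format = "castsim-sidecar-v1",
    package_version = as.character(utils::packageVersion("castsim")),
    study = design$study, seed = as.integer(seed), agent_id = agent_id,
    n_trials = design$n_trials, blocks = design$blocks)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# agent fields serialised to the cohort CSV (everything scalar)
.AGENT_FIELDS <- c("id", "math_anxiety", "reading_anxiety", "trait_anxiety",
                   "test_anxiety", "competence_math", "competence_word",
                   "psychometric_slope", "lapse", "cost_base_math",
                   "cost_base_word", "anxiety_cost_slope",
                   "choice_temperature", "perceived_acc_easy",
                   "perceived_acc_hard", "guess_threshold", "timeout_prob",
                   "rt_choose_meanlog", "rt_choose_sdlog",
                   "rt_solve_meanlog", "rt_solve_sdlog",
                   "rt_guess_meanlog", "rt_guess_sdlog")

#' Write / read a cohort of agents
#'
#' One CSV row per agent carrying every \code{agent_params} field, so a
#' simulated cohort can be re-run exactly from file.
#'
#' @param agents List of \code{agent_params}.
#' @param path File path.
#' @return \code{write_cohort}: the path, invisibly; \code{read_cohort}:
#'   a list of \code{agent_params}.
#' @export
write_cohort <- function(agents, path) {
  rows <- lapply(agents, function(a) {
    as.data.frame(a[.AGENT_FIELDS], stringsAsFactors = FALSE)
  })
  .write_versioned_csv(do.call(rbind, rows), path, "cohort")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- .read_versioned_csv(path)
  missing <- setdiff(.AGENT_FIELDS, names(df))
  if (length(missing)) {
    stop("cohort schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(j) {
    do.call(agent_params, as.list(df[j, .AGENT_FIELDS]))
  })
}

#' Write a participant-summary table
#'
#' @param summaries data.frame from \code{\link{summarize_participants}}.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  .write_versioned_csv(summaries, path, "summary")
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  .read_versioned_csv(path)
}

# one hand-checkable math trial row
.toy_trial <- function(id, trial, reward, choice, level = 4L,
                       correct = TRUE) {
  data.frame(participant_id = id, study = "study1", block_index = 1L,
             trial_index = trial, is_practice = FALSE, domain = "math",
             is_no_choice = FALSE, hard_reward_offered = reward,
             choice = choice, choice_rt = 1.2,
             difficulty_level = if (choice == "hard") level else 1L,
             problem_id = sprintf("math-%05d", trial),
             solve_correct = correct, solve_rt = 3.0,
             solve_timeout = FALSE,
             reward_earned = if (correct)
               as.integer(if (choice == "hard") reward else 2L) else 0L,
             stringsAsFactors = FALSE)
}

#' Bundled toy fixtures
#'
#' Deterministic miniature inputs used throughout the test suite:
#' \describe{
#'   \item{exclusion_summaries}{6 participants whose easy-math accuracies
#'     are 0.95, 0.71, 0.69, 0.70, 0.50, 0.90 (easy word all 0.90): the
#'     strict below-70\% rule keeps 4 and excludes 2.}
#'   \item{hcp_log}{A deliberately unbalanced 9-trial math log: the
#'     4/5/6-cent cells hold 2/3/4 trials with 2/1/1 hard choices, so the
#'     mean-of-conditions HCP is (1 + 1/3 + 1/4)/3 = 19/36 while the
#'     pooled proportion is 4/9.}
#'   \item{mini_cohort}{20 agents from the default trait world with a
#'     known anxiety-cost slope of 0.5.}
#' }
#'
#' @param seed Integer seed (affects only \code{mini_cohort}).
#' @return Named list of the three fixtures.
#' @export
make_fixtures <- function(seed = 1) {
  exclusion_summaries <- data.frame(
    participant_id = sprintf("fx%02d", 1:6),
    math_easy_accuracy = c(0.95, 0.71, 0.69, 0.70, 0.50, 0.90),
    word_easy_accuracy = rep(0.90, 6),
    stringsAsFactors = FALSE)

  hcp_rows <- list(
    .toy_trial("fxh", 1L, 4L, "hard"), .toy_trial("fxh", 2L, 4L, "hard"),
    .toy_trial("fxh", 3L, 5L, "hard"), .toy_trial("fxh", 4L, 5L, "easy"),
    .toy_trial("fxh", 5L, 5L, "easy"), .toy_trial("fxh", 6L, 6L, "hard"),
    .toy_trial("fxh", 7L, 6L, "easy"), .toy_trial("fxh", 8L, 6L, "easy"),
    .toy_trial("fxh", 9L, 6L, "easy"))
  hcp_log <- do.call(rbind, hcp_rows)

  cfg <- cohort_config(n = 20, seed = as.integer(seed))
  mini_cohort <- traits_to_agents(
    generate_traits(cfg),
    default_calibration(anxiety_cost_slope = 0.5),
    seed = as.integer(seed) + 1L)

  list(exclusion_summaries = exclusion_summaries,
       hcp_log = hcp_log,
       mini_cohort = mini_cohort)
}
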