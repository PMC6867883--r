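# Statistical layer.
#
# Correlations are reported with Fisher-z confidence intervals and
# t-distribution p-values; the sample-size rule inverts the Fisher-z
# normal approximation. The domain x anxiety interaction model is a
# fixed-stratum normal maximum-likelihood regression (two rows per
# participant, math as the reference domain), and the nonnormal-HCP
# robustness check is a binomial logistic regression on (hard choices,
# eligible trials) counts.

#' Pearson correlation with a Fisher-z confidence interval
#'
#' r is the sample Pearson correlation; the (1 - alpha) CI is
#' \code{tanh(atanh(r) +- z / sqrt(n - 3))}; the two-sided p-value comes
#' from \code{t = r sqrt((n-2)/(1-r^2))} on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length n >= 4 (pairs with missing
#'   values are dropped).
#' @param alpha Two-sided significance level (default 0.05).
#' @return List of class \code{correlation_result}: \code{r}, \code{df},
#'   \code{ci_low}, \code{ci_high}, \code{p}, \code{n}.
#' @export
pearson_ci <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  z <- stats::qnorm(1 - alpha / 2)
  zr <- atanh(r)
  ci <- tanh(zr + c(-1, 1) * z / sqrt(n - 3))
  df <- n - 2L
  tstat <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(r = r, df = df, ci_low = ci[1], ci_high = ci[2],
                 p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson's r(%d) = %.3f; 95%% CI, %.3f to %.3f; p = %.3g\n",
              x$df, x$r, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Sample size to detect a correlation
#'
#' Fisher-z normal-approximation rule:
#' \code{n = round(((z_(1-alpha/2) + z_power) / atanh(rho))^2 + 3)}.
#' Detecting rho = 0.2 with 80\% power at alpha = 0.05 needs n = 194;
#' with 95\% power, n = 319.
#'
#' @param rho Expected correlation, 0 < |rho| < 1.
#' @param power Desired power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Required sample size (integer, floored at 4).
#' @examples
#' sample_size_for_r(0.2, 0.80, 0.05)  # 194
#' @export
sample_size_for_r <- function(rho, power, alpha = 0.05) {
  if (!is.finite(rho) || rho == 0 || abs(rho) >= 1) {
    stop("rho must satisfy 0 < |rho| < 1", call. = FALSE)
  }
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1)
  n <- round(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
                atanh(abs(rho)))^2 + 3)
  max(as.integer(n), 4L)
}

# shared coefficient-table builder
.coef_table <- function(fit, alpha = 0.05) {
  sm <- summary(fit)
  co <- stats::coef(sm)
  crit <- stats::qt(1 - alpha / 2, df = stats::df.residual(fit))
  data.frame(term = rownames(co), beta = co[, 1], se = co[, 2],
             statistic = co[, 3], p = co[, 4],
             ci_low = co[, 1] - crit * co[, 2],
             ci_high = co[, 1] + crit * co[, 2],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stack participant summaries into the long (two rows each) layout
#'
#' One row per participant per domain, with domain-matched covariates, as
#' required by \code{\link{interaction_model}}. Trait and stratum columns
#' are merged in from \code{traits} by \code{participant_id}.
#'
#' @param summaries data.frame from \code{\link{summarize_participants}}.
#' @param traits data.frame with \code{participant_id},
#'   \code{math_anxiety}, and any stratum columns to carry along.
#' @return Long data.frame with columns \code{participant_id},
#'   \code{domain}, \code{hcp}, \code{adl}, \code{easy_accuracy},
#'   \code{hard_accuracy}, \code{easy_rt}, \code{hard_rt}, plus the
#'   merged trait/stratum columns.
#' @export
build_long_table <- function(summaries, traits) {
  pick <- function(dom) {
    data.frame(participant_id = summaries$participant_id,
               domain = dom,
               hcp = summaries[[paste0(dom, "_hcp")]],
               adl = summaries[[paste0(dom, "_adl")]],
               easy_accuracy = summaries[[paste0(dom, "_easy_accuracy")]],
               hard_accuracy = summaries[[paste0(dom, "_hard_accuracy")]],
               easy_rt = summaries[[paste0(dom, "_easy_rt")]],
               hard_rt = summaries[[paste0(dom, "_hard_rt")]],
               stringsAsFactors = FALSE)
  }
  long <- rbind(pick("math"), pick("word"))
  merge(long, traits, by = "participant_id", sort = TRUE)
}

#' Domain x anxiety interaction regression
#'
#' Normal maximum-likelihood regression of HCP on domain, math anxiety,
#' their interaction, the domain-matched solving covariates, and
#' categorical strata as fixed intercepts. Math is the reference domain,
#' so the math-anxiety main effect is the math-domain slope and a
#' positive interaction coefficient means the word-domain slope is less
#' negative — the math-specific avoidance signature.
#'
#' @param long data.frame from \code{\link{build_long_table}}.
#' @param covariates Column names entered as fixed effects alongside
#'   domain, anxiety, and their interaction.
#' @param strata Categorical columns entered as fixed intercepts (use
#'   \code{character(0)} for none).
#' @param alpha CI level.
#' @return List of class \code{regression_result}: \code{coefficients}
#'   (term, beta, se, statistic, p, ci_low, ci_high), \code{df},
#'   \code{adjusted_r2}.
#' @export
interaction_model <- function(long,
                              covariates = c("easy_accuracy",
                                             "hard_accuracy", "easy_rt",
                                             "hard_rt", "adl"),
                              strata = c("age_band", "gender"),
                              alpha = 0.05) {
  stopifnot(all(c("hcp", "domain", "math_anxiety") %in% names(long)))
  long$domain <- factor(long$domain, levels = c("math", "word"))
  strata <- intersect(strata, names(long))
  for (s in strata) long[[s]] <- factor(long[[s]])
  rhs <- c("domain * math_anxiety", covariates, strata)
  f <- stats::as.formula(paste("hcp ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(f, data = long)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    stop("rank-deficient design; collinear terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(list(coefficients = .coef_table(fit, alpha),
                 df = stats::df.residual(fit),
                 adjusted_r2 = summary(fit)$adj.r.squared,
                 model = f),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> df = %d, adjusted R^2 = %.2f%%\n",
              x$df, 100 * x$adjusted_r2))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Binomial regression of hard-choice counts
#'
#' Logistic regression of (hard choices k out of m eligible trials) on
#' covariates, the robustness companion to the normal model for the
#' skewed HCP distribution. Complete or quasi-complete separation is
#' reported as an error naming the boundary.
#'
#' @param counts data.frame with columns \code{k} (hard choices),
#'   \code{m} (eligible trials), and covariate columns.
#' @param covariates Covariate column names (default: all others).
#' @param alpha CI level.
#' @return A \code{regression_result} with log-odds coefficients (the
#'   \code{adjusted_r2} slot carries McFadden's pseudo-R^2).
#' @export
binomial_hcp_model <- function(counts, covariates = NULL, alpha = 0.05) {
  stopifnot(all(c("k", "m") %in% names(counts)),
            all(counts$k >= 0), all(counts$k <= counts$m))
  if (is.null(covariates)) {
    covariates <- setdiff(names(counts), c("k", "m", "participant_id"))
  }
  if (all(counts$k == counts$m) || all(counts$k == 0)) {
    stop("separation: all responses on one boundary (k = ",
         if (all(counts$k == 0)) "0" else "m", ")", call. = FALSE)
  }
  f <- stats::as.formula(paste("cbind(k, m - k) ~",
                               paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(f, family = stats::binomial(),
                                     data = counts))
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    big <- names(which(abs(stats::coef(fit)) > 15))
    stop("separation suspected; runaway coefficient(s): ",
         paste(big, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  co <- stats::coef(sm)
  z <- stats::qnorm(1 - alpha / 2)
  tab <- data.frame(term = rownames(co), beta = co[, 1], se = co[, 2],
                    statistic = co[, 3], p = co[, 4],
                    ci_low = co[, 1] - z * co[, 2],
                    ci_high = co[, 1] + z * co[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  null_dev <- fit$null.deviance
  structure(list(coefficients = tab, df = stats::df.residual(fit),
                 adjusted_r2 = 1 - fit$deviance / null_dev,
                 model = f),
            class = "regression_result")
}

#' Test-retest reliability of the derived measures
#'
#' Pearson correlations (with Fisher-z CIs) between two sessions'
#' summaries, matched on participant id, one per measure.
#'
#' @param session1,session2 data.frames from
#'   \code{\link{summarize_participants}}.
#' @param measures Measure columns to correlate.
#' @param alpha CI level.
#' @return Named list of \code{correlation_result}, one per measure.
#' @export
test_retest <- function(session1, session2,
                        measures = c("math_hcp", "word_hcp",
                                     "math_adl", "word_adl"),
                        alpha = 0.05) {
  merged <- merge(session1, session2, by = "participant_id",
                  suffixes = c(".t1", ".t2"))
  if (!nrow(merged)) {
    stop("no participants shared between the two sessions", call. = FALSE)
  }
  out <- lapply(measures, function(m) {
    pearson_ci(merged[[paste0(m, ".t1")]], merged[[paste0(m, ".t2")]],
               alpha = alpha)
  })
  names(out) <- measures
  out
}
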