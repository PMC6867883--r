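test_that("pearson_ci reproduces the Fisher-z chain on a fixed toy set", {
  # 12-point toy data; oracle computed from the raw formulas inline
  x <- c(1.2, 2.4, 3.1, 4.8, 5.0, 6.3, 7.7, 8.1, 9.4, 10.2, 11.8, 12.5)
  y <- c(2.0, 1.1, 4.2, 3.9, 6.1, 5.8, 7.0, 9.2, 8.8, 11.0, 10.4, 13.1)
  n <- 12L
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  z <- qnorm(0.975)
  ci_hand <- tanh(atanh(r_hand) + c(-1, 1) * z / sqrt(n - 3))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), n - 2)

  res <- pearson_ci(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(c(res$ci_low, res$ci_high), ci_hand, tolerance = 1e-12)
  expect_equal(res$p, p_hand, tolerance = 1e-12)
  expect_identical(res$df, n - 2L)
})

test_that("pearson_ci handles identity, null, and degenerate input", {
  x <- 1:20
  res <- pearson_ci(x, x * 2 + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)

  set.seed(300)
  res0 <- pearson_ci(rnorm(10000), rnorm(10000))
  expect_lt(abs(res0$r), 0.03)

  expect_error(pearson_ci(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(pearson_ci(1:3, 3:1), "at least 4")
})

test_that("CI brackets r and tightens with n", {
  set.seed(301)
  widths <- vapply(c(10, 100, 1000), function(n) {
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- pearson_ci(x, y)
    expect_lte(res$ci_low, res$r)
    expect_gte(res$ci_high, res$r)
    res$ci_high - res$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("sample size rule gives the published 194 and 319", {
  expect_identical(sample_size_for_r(0.2, 0.80, 0.05), 194L)
  expect_identical(sample_size_for_r(0.2, 0.95, 0.05), 319L)
  expect_gte(sample_size_for_r(0.9999, 0.8, 0.05), 4L)
  expect_error(sample_size_for_r(0, 0.8, 0.05), "rho")

  # monotonicities
  expect_gt(sample_size_for_r(0.1, 0.8, 0.05),
            sample_size_for_r(0.3, 0.8, 0.05))
  expect_gt(sample_size_for_r(0.2, 0.95, 0.05),
            sample_size_for_r(0.2, 0.80, 0.05))
  expect_gt(sample_size_for_r(0.2, 0.8, 0.01),
            sample_size_for_r(0.2, 0.8, 0.10))
})

# synthetic long table straight from a known linear model (no simulator)
make_long <- function(n, b_math, b_word, seed, sd_noise = 0.1) {
  set.seed(seed)
  anx <- runif(n, 1, 5)
  mk <- function(dom, b) {
    data.frame(participant_id = sprintf("p%03d", 1:n), domain = dom,
               hcp = pmin(pmax(0.7 + b * (anx - 3) +
                                 rnorm(n, 0, sd_noise), 0), 1),
               adl = rnorm(n, 4, 0.5), easy_accuracy = runif(n, 0.9, 1),
               hard_accuracy = runif(n, 0.6, 0.8),
               easy_rt = rnorm(n, 3, 0.3), hard_rt = rnorm(n, 4, 0.3),
               math_anxiety = anx,
               age_band = sample(c("18-25", "26-35"), n, TRUE),
               gender = sample(c("female", "male"), n, TRUE),
               stringsAsFactors = FALSE)
  }
  rbind(mk("math", b_math), mk("word", b_word))
}

test_that("interaction model recovers sign and covers a null effect", {
  # math-only negative anxiety effect: interaction (word - math) positive
  long <- make_long(150, b_math = -0.08, b_word = 0, seed = 310)
  res <- interaction_model(long)
  tab <- res$coefficients
  inter <- tab[tab$term == "domainword:math_anxiety", ]
  expect_gt(inter$beta, 0)
  expect_gt(inter$ci_low, 0)
  main <- tab[tab$term == "math_anxiety", ]
  expect_lt(main$beta, 0)   # math is the reference domain
  expect_true("(Intercept)" %in% tab$term)
  expect_true(all(tab$ci_low <= tab$beta & tab$beta <= tab$ci_high))

  # null interaction: CI covers 0 in >= 93 of 100 synthetic cohorts
  covered <- 0L
  for (k in 1:100) {
    lg <- make_long(60, b_math = -0.05, b_word = -0.05, seed = 400 + k)
    ci <- interaction_model(lg)$coefficients
    ci <- ci[ci$term == "domainword:math_anxiety", ]
    if (ci$ci_low <= 0 && ci$ci_high >= 0) covered <- covered + 1L
  }
  expect_gte(covered, 93L)
})

test_that("interaction model flags rank deficiency by name", {
  long <- make_long(50, -0.05, 0, seed = 320)
  long$dupe <- long$adl            # exact copy of a covariate
  expect_error(interaction_model(long, covariates = c("adl", "dupe")),
               "collinear.*dupe")
})

test_that("binomial regression matches the generating sign and flags separation", {
  set.seed(330)
  n <- 200
  anx <- runif(n, 1, 5)
  m <- rep(60L, n)
  p <- plogis(1.5 - 0.5 * anx)
  counts <- data.frame(k = rbinom(n, m, p), m = m, math_anxiety = anx)
  res <- binomial_hcp_model(counts)
  tab <- res$coefficients
  beta <- tab[tab$term == "math_anxiety", ]
  expect_lt(beta$beta, 0)
  expect_lt(beta$ci_high, 0)
  expect_equal(beta$beta, -0.5, tolerance = 0.1)

  # boundary data: every participant always chose hard
  sep <- data.frame(k = m, m = m, math_anxiety = anx)
  expect_error(binomial_hcp_model(sep), "separation")

  # null coverage at roughly the nominal rate
  covered <- 0L
  for (k in 1:100) {
    set.seed(500 + k)
    cnt <- data.frame(k = rbinom(80, 60, 0.6), m = rep(60L, 80),
                      math_anxiety = runif(80, 1, 5))
    ci <- binomial_hcp_model(cnt)$coefficients
    ci <- ci[ci$term == "math_anxiety", ]
    if (ci$ci_low <= 0 && ci$ci_high >= 0) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("test-retest: identity gives r = 1, disjoint ids error, and
           stable agents correlate across sessions", {
  s1 <- data.frame(participant_id = sprintf("p%02d", 1:20),
                   math_hcp = runif(20), word_hcp = runif(20),
                   math_adl = runif(20, 2, 7), word_adl = runif(20, 2, 7))
  res <- test_retest(s1, s1)
  expect_equal(res$math_hcp$r, 1)
  expect_equal(res$word_adl$r, 1)

  s2 <- s1
  s2$participant_id <- sprintf("q%02d", 1:20)
  expect_error(test_retest(s1, s2), "shared")

  # same agents, fresh seeds: positive reliability on the retest design
  agents <- traits_to_agents(generate_traits(cohort_config(60, seed = 340)),
                             default_calibration(anxiety_cost_slope = 0.3),
                             seed = 341)
  d <- build_design("study1R")
  bank <- test_bank()
  t1 <- summarize_participants(run_cohort(agents, d, bank, seed = 342,
                                          include_practice = FALSE))
  t2 <- summarize_participants(run_cohort(agents, d, bank, seed = 343,
                                          include_practice = FALSE))
  rel <- test_retest(t1, t2)
  expect_gt(rel$math_hcp$r, 0)
  expect_gt(rel$math_adl$r, 0)
})
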