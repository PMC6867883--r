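---
title: "Simulating effort-based choice in the choose-and-solve task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating effort-based choice in the choose-and-solve task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(castsim)
```

## The task and what the package simulates

The choose-and-solve task (CAST) measures effort-based decision-making in
a specific cognitive domain. On every trial a participant chooses, within
3 s, between an *easy* card that always pays 2 cents and a *hard* card
that pays 2–6 cents, then has 7 s to solve a three-alternative problem of
the chosen kind (responses locked out for the first 1.5 s); the reward is
credited only if the answer is correct. Failing to choose in time routes
to an easy problem worth 1 cent. Easy problems always come from the
easiest of seven difficulty levels; hard-problem difficulty follows a
2-up-1-down staircase per domain (math, word): up one level after two
consecutive correct answers, down one after any error, bounded to [2, 7],
starting at 4.

The staircase is the design's central trick. Its equilibrium accuracy
solves $p^2 = 1/2$, so every participant is held near
$\sqrt{0.5} \approx 70.7\%$ correct on hard problems *regardless of
competence*, which decouples choice behaviour from experienced failure
rates. With believed accuracies of 0.95 (easy) and 0.70 (hard), the hard
card's expected value $0.70 \times r$ exceeds the easy card's
$0.95 \times 2 = 1.9$ for $r \ge 3$; the canonical outcome measure, the
**hard choice probability (HCP)**, is the mean of the per-condition
hard-choice proportions in the 4-, 5-, and 6-cent conditions. The
**average difficulty level (ADL)** — the mean staircase level over all
hard problems encountered — serves as a competence proxy.

`castsim` re-creates this machinery for fully synthetic cohorts so that
the derived measures, the design arithmetic, and the headline
anxiety-avoidance effect can be exercised end to end with known ground
truth.

## The agent model

An agent solves and chooses by two simple mechanisms.

**Solving** is a psychometric function of latent item difficulty $d$:
$$p(\text{correct}) = \tfrac13 + (\tfrac23 - \lambda)\,
\sigma\!\big(s\,(c - d)\big),$$
with competence $c$, slope $s$ (default 1), lapse $\lambda$ (default
0.02), a 1/3 floor from the three answer options, and a $1-\lambda$
ceiling. Defaults ($c = 4.3$) put level-1 accuracy near 96% — matching
the "above 90%" easy regime — and the staircase equilibrium near level 4.

**Choosing** is a cost–benefit softmax. Each card's subjective value is
believed accuracy × reward minus an effort cost that grows linearly with
difficulty level, in cents so the comparison is dimensionally coherent:
$$\mathrm{SV}_{hard} = 0.70\,r - \kappa_{dom} L, \qquad
\mathrm{SV}_{easy} = 0.95 \times 2 - \kappa_{dom},$$
and the hard card is chosen with probability
$\sigma((\mathrm{SV}_{hard} - \mathrm{SV}_{easy})/\tau)$, temperature
$\tau = 0.5$ cents by default. The hypothesis machinery lives in one
parameter: the math cost rate is
$\kappa_{math} = \kappa_0 + \beta_{anx}(\text{math anxiety} - 1)$ while
$\kappa_{word} = \kappa_0$, so anxiety discounts hard *math* only. Agent
beliefs stay at the design constants 0.95/0.70 rather than tracking
experienced accuracy, because the task's normative analysis is built on
those constants; a choose-phase timeout occurs with a small fixed
probability (0.01), not anxiety-linked.

A **fast-guessing mode** models the reported pattern of anxious
participants spending less time (and scoring worse) on hard math: when
the subjective cost of the hard problem exceeds a threshold, the agent
answers quickly at chance. The switch is hard rather than graded so tests
can identify it, and it is *off by default* (`guess_threshold = Inf`) so
the calibrated anxiety-to-HCP channel stays clean; the recovery tests
enable it explicitly.

Response times are log-normal, clipped to the 3-s choose limit and to
[1.5 s, 7 s] for solves; a raw solve draw beyond 7 s is a timeout, which
counts as an incorrect answer (feedback shows the correct answer, so the
trial is a scored miss) both for accuracy and for the staircase.

## The synthetic cohort: a stated world

Traits are drawn from a latent multivariate normal, affine-mapped to
their questionnaire scales (math/reading anxiety 1–5, trait/test anxiety
20–80) and clipped. The default correlation matrix makes math anxiety
positively correlated with test (0.5), trait (0.35), and reading (0.3)
anxiety — the qualitative structure reported for such samples; the source
studies do not publish the numeric covariances in their main text, so
these values are a documented choice, not an estimate. Means and SDs
(math anxiety 2.2 ± 0.8, reading 1.8 ± 0.6, trait 40 ± 10, test 42 ± 11)
are plausible crowd-sourced-sample values chosen once. Demographic strata
(age band, gender) are uniform categorical draws that exist only to
exercise the covariate-adjusted regression paths.

Agents inherit competence $c \sim N(4.3, 0.5)$ per domain, with math
competence coupled to math anxiety at $-0.15$ per anxiety unit by
default, reproducing the negative anxiety–ADL association; word
competence is independent of math anxiety. Per-domain base costs get
independent agent-level noise ($0.1 \pm 0.15$, truncated at 0) so that
anxiety is not the only source of choice heterogeneity — without it the
latent anxiety–HCP correlation would be implausibly near 1 at any
nonzero slope.

What the generator does **not** emulate: learning or fatigue dynamics
(the empirical block slopes argue against fatigue), item-level content
effects, belief updating from feedback (available as an option, off by
default), anxiety-linked choose-phase timeouts, and realistic population
marginals of the questionnaires. A green recovery test therefore
establishes that the pipeline measures what the generative model puts in
— not that humans behave like these agents.

## Calibrating the headline effect

`calibrate_effect()` finds the anxiety cost slope $\beta_{anx}$ giving a
requested population correlation between math anxiety and math HCP. Two
numerical choices matter:

1. **Closed-form objective.** The staircase pins each agent near its
   equilibrium level $L^\* = c - \sigma^{-1}(q)/s$ (where $q$ rescales
   $\sqrt{0.5}$ between the psychometric floor and ceiling), so expected
   HCP has a closed form; adding the binomial measurement variance
   implied by the design's per-condition trial counts gives the expected
   *observed* correlation without simulating. Bisection on this objective
   over 2,000 trait draws is fast and deterministic.
2. **Simulation polish.** The closed form ignores staircase transients:
   an agent that rarely chooses hard lingers near the level-4 start
   instead of its equilibrium, which biases the achieved correlation by a
   few hundredths. One Newton step against a fully simulated cohort
   (n = 1500), with the derivative taken from the closed form, removes
   the bias. At target $-0.34$ (the exploratory study's value) the
   calibrated slope reproduces $r = -0.33 \pm 0.01$ across independent
   simulated cohorts, within the ±0.03 calibration contract.

Calibration touches only the math cost channel, so the word-HCP
correlation with math anxiety stays within sampling error of zero — the
math-specificity property that the acceptance suite verifies at n = 142
over 50 replicates.

## Scoring conventions and degenerate inputs

Several denominators are under-specified in prose descriptions of such
tasks; `castsim` fixes them as follows and applies them consistently:
practice trials never score; choice-timeout trials are excluded from HCP
(the participant never faced the 4/5/6-cent decision) and from accuracy;
solve timeouts count as incorrect answers everywhere, consistent with the
staircase treatment; RT summaries average answered trials only;
no-choice trials feed accuracy, RT, and ADL but never HCP. HCP is
reported as the mean of the three condition proportions (the pooled
proportion is exposed as an option; the two coincide under balanced
schedules). An empty reward cell makes HCP an error naming the cell at
the single-measure level and an `NA` in cohort summaries; exclusion is
strict (`accuracy < 0.70`), and an undefined easy accuracy excludes with
a warning.

The interaction analysis approximates the original mixed model with
random intercepts for demographic categories as a fixed-stratum normal
ML regression: with categorical strata as the only grouping, fixed
intercepts reproduce the mean structure that the coefficients test.
Math is the reference domain, so the anxiety main effect is the
math-domain slope and a positive domain × anxiety coefficient is the
math-specificity signature. Independent variables are not transformed,
p-values are two-sided, and no multiplicity correction is applied.

## Worked example

```{r example, eval = FALSE}
design <- build_design("study2")
cfg <- cohort_config(n = 332, seed = 1)
agents <- traits_to_agents(generate_traits(cfg),
                           default_calibration(anxiety_cost_slope = 0.08),
                           seed = 2)
log <- run_cohort(agents, design, seed = 3)
summaries <- apply_exclusions(summarize_participants(log))$kept
traits <- generate_traits(cfg)
merged <- merge(summaries, traits, by = "participant_id")
pearson_ci(merged$math_anxiety, merged$math_hcp)
```

## Known limitations

* The normative claim that the hard card is worth choosing "above 3
  cents" conflicts with strict expected-value arithmetic at exactly 3
  cents ($3 \times 0.70 = 2.10 > 1.90$); the package follows the
  operational HCP definition (4/5/6-cent conditions only) and leaves the
  boundary case undecided, as the task description does.
* Whether a level-raising correct answer also resets the streak is a
  convention (reset chosen, the standard one); sequences that alternate
  exactly at the boundary would differ under the other convention.
* The per-level allocation of the original validated item pools is
  unpublished; banks default to near-uniform allocation with the
  remainder on lower levels.
* Word items are abstract (latent difficulty only); only math items have
  a concrete rendered form (missing-digit multiplication with operand
  size growing in level).
* Calibration is defined on the asymptotic cohort correlation; at small
  n the observed effect varies with sampling noise, which is exactly what
  the recovery tests quantify.
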