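# Shared builders for the suite: one modest bank and a few agent presets.

test_bank <- function(seed = 42) generate_bank(140, 140, seed = seed)

# near-deterministic value maximiser: no cost, almost-zero temperature
ev_agent <- function(...) {
  agent_params(cost_base_math = 0, cost_base_word = 0,
               anxiety_cost_slope = 0, choice_temperature = 1e-6,
               timeout_prob = 0, ...)
}

# simulate a fixed-p solver through the reference staircase updater
simulate_staircase_fixed_p <- function(p, n, seed = 1) {
  set.seed(seed)
  st <- init_staircase()
  correct <- logical(n)
  for (i in seq_len(n)) {
    correct[i] <- stats::runif(1) < p
    st <- staircase_update(st, correct[i])
  }
  list(state = st, accuracy = mean(correct))
}
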