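# Shared fixtures: the baseline model and lazily cached steady-state
# simulations, so expensive runs are shared across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

baseline_model <- function() default_model()

baseline_waveform <- function() {
  cached("baseline_waveform", run_simulation(default_model()))
}

baseline_metrics <- function() {
  cached("baseline_metrics", cycle_metrics(baseline_waveform()))
}

m20_waveform <- function() {
  cached("m20_waveform",
         run_simulation(apply_injury(default_model(), 20)))
}

m20_metrics <- function() {
  cached("m20_metrics", cycle_metrics(m20_waveform()))
}

injury_sweep_table <- function() {
  cached("injury_sweep", run_injury_sweep(default_model()))
}

# a random admissible state in the broad physiologic range, for RHS
# property tests
random_state <- function(m, seed) {
  set.seed(seed)
  s <- default_initial_state(m)
  s[c("V_lv", "V_rv")] <- runif(2, 30e3, 150e3)
  s[grep("^Q_", names(s))] <- runif(4, -1e4, 5e5)
  s[grep("^P_", names(s))] <- runif(9, 100, 20000)
  s
}
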