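# Shared, lazily computed simulations so the expensive steady-state run is
# done once per test session.

.sim_cache <- new.env(parent = emptyenv())

baseline_sim <- function() {
  if (is.null(.sim_cache$base)) {
    .sim_cache$base <- run_to_steady_state(cvs_params())
  }
  .sim_cache$base
}

ivco_run <- function() {
  if (is.null(.sim_cache$ivco)) {
    .sim_cache$ivco <- run_ivco(cvs_params(), baseline = baseline_sim())
  }
  .sim_cache$ivco
}

total_volume <- function(traces) {
  rowSums(traces[, c("V_la", "V_lv", "V_rv", "V_ao", "V_vc", "V_pa", "V_pu")])
}

shoelace <- function(x, y) {
  m <- length(x)
  sum(x * y[c(2:m, 1)] - x[c(2:m, 1)] * y) / 2
}
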