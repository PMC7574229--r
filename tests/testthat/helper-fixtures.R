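# Shared fixtures, built once per test run.

# A tiny simulated herd: 4 cows, one session, two recorded hours.
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cf <- sim_config(n_cows = 4L, n_sessions = 2L, days_per_session = 1L,
                       recorded_hours = c(9L, 11L), seed = 42L)
      cache <<- simulate_herd(cf)
    }
    cache
  }
})

tiny_projected <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- project_to_metric(filter_hdop(tiny_sim()$gps))
    }
    cache
  }
})

accel_provider_for <- function(sim) {
  function(id, t0) tryCatch(sim_accel(sim, id, t0), error = function(e) NULL)
}

# Random 2-D trajectory (correlated random walk) for property tests.
random_walk <- function(n, step_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(x = cumsum(rnorm(n, 0, step_sd)), y = cumsum(rnorm(n, 0, step_sd)),
       t = seq_len(n) - 1)
}
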