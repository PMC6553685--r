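# shared fixtures: built in code, small and deterministic

baseline_config <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- scenario_config()
    memo
  }
})

baseline_spin <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- spin_up(baseline_config())
    memo
  }
})

# tiny three-point historical series ending at 2014
toy_history <- function(end_rate = 9.8) {
  data.frame(year = c(1800, 1900, 2014),
             emissions_gtc = c(0.1, 2, end_rate))
}

# a schedule that is identically zero (equilibrium forcing)
zero_schedule <- function() {
  make_schedule(data.frame(year = c(1800, 2014), emissions_gtc = c(0, 0)),
                eps_max = 0, s = 50)
}

# random social parameter tuples in raw form, reproducible
random_raw_params <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    social_params(kappa = runif(1, 0.01, 0.5),
                  delta = runif(1, 0, 2),
                  omega = runif(1, 0.5, 5),
                  Tc = runif(1, 1, 4),
                  alpha = runif(1, -1, 2), gamma = runif(1, -1, 2),
                  c = runif(1, 0, 4), ftilde_max = runif(1, 0.2, 3))
  })
}
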