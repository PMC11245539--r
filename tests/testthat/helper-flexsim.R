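# shared fixtures; heavyweight sessions are simulated once per test run and
# cached so several test files can interrogate the same training history
.flex_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .flex_cache)) {
    assign(key, force(expr), envir = .flex_cache)
  }
  get(key, envir = .flex_cache)
}

# a small VTA-only configuration for fast baseline checks
vta_only_config <- function(...) {
  cfg <- flex_config(...)
  cfg2 <- unclass(cfg)
  cfg2$network$columns <- character(0)
  structure(cfg2, class = "flex_config")
}

# silent single-population params for unit tests of the integrator
test_params <- function(n = 1, type = "E", noise_sd = 0, noise_mean = 0,
                        cfg = flex_config()) {
  population_params(n, type, s_classes = "E", noise_mean = noise_mean,
                    noise_sd = noise_sd, cfg = cfg)
}

# standard 30-trial trace-conditioning session (the Fig-6-style run), shared
# by the interval-learning, convergence and integrated-dopamine tests
standard_session <- function() {
  cached("standard_session", trace_conditioning(seed = 11, n_trials = 30))
}

# a probe trial on the trained network, plasticity off
standard_probe <- function() {
  cached("standard_probe", {
    s <- standard_session()
    trace_conditioning(net = s$network, seed = 210, n_trials = 1,
                       learn = FALSE)
  })
}

# naive US-only session for the reinforcement baseline
us_only_session <- function(n_trials = 5) {
  cached("us_only", {
    net <- build_flex_network(flex_config(), seed = 11)
    proto <- trial_protocol(1300, list(stimulus_event("US", 1100, 100)),
                            n_trials)
    run_session(net, proto, seed = 31, learn = FALSE)
  })
}

# two-column network pre-trained on CS1 only, shared by the blocking and
# unblocking checks
two_col_trained <- function() {
  cached("two_col_trained", {
    cfg <- flex_config(network = list(columns = c("CS1", "CS2")))
    net <- build_flex_network(cfg, seed = 41)
    trace_conditioning(net = net, seed = 41, n_trials = 20)$network
  })
}
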