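# protocol-level behaviour of the spiking model.  The 30-trial standard
# session is simulated once (helper cache) and interrogated from several
# angles; auxiliary protocols run at reduced trial counts from the shared
# trained network (the vignette documents the problem sizes).

test_that("reproducibility: same config and seed give identical sessions", {
  cfg <- flex_config()
  n1 <- build_flex_network(cfg, seed = 21)
  n2 <- build_flex_network(cfg, seed = 21)
  proto <- trial_protocol(600, list(stimulus_event("CS1", 100, 100)), 2)
  s1 <- run_session(n1, proto, seed = 21, record_spikes = TRUE)
  s2 <- run_session(n2, proto, seed = 21, record_spikes = TRUE)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$weight_curves, s2$weight_curves)
})

test_that("no-event trial keeps D(t) in the neutral band almost everywhere", {
  net <- build_flex_network(flex_config(), seed = 22)
  out <- run_session(net, trial_protocol(1300, list(), 1), seed = 22,
                     learn = FALSE)
  expect_gt(mean(out$D == 0), 0.95)
})

test_that("naive network: dopamine responds to the reward, not the cue", {
  us <- us_only_session()
  D <- us$D
  # positive response in the reward window on every naive trial
  expect_true(all(apply(D[1090:1300, ], 2, max) > 3))
  # nothing before the reward
  expect_true(all(abs(D[1:1000, ]) < 2))
})

test_that("training grows all three plastic weight means", {
  s <- standard_session()
  w <- s$weight_curves
  final <- w[w$trial == 30, ]
  init <- flex_config()$network$init_weights
  expect_gt(final$mean_weight[final$group == "timer_rec:CS1"],
            init$timer_rec)
  expect_gt(final$mean_weight[final$group == "cs_da:CS1"], init$cs_da)
  expect_gt(final$mean_weight[final$group == "m_gaba:CS1"], init$m_gaba)
})

test_that("timer envelope grows across training toward the cue-reward delay", {
  s <- standard_session()
  dur <- vapply(c(1, 10, 30), function(tr) {
    timer_duration(s$rates[, "CS1:T", tr], threshold_fraction = 0.1)
  }, 0)
  expect_lt(dur[1], 600)                  # naive transient is short
  expect_gt(dur[2], dur[1])               # grows over training
  expect_gt(dur[3], 800)                  # spans most of the 1000 ms delay
})

test_that("intermediate trials: cue response potentiated before reward depressed", {
  s <- standard_session()
  D5_cs <- max(s$D[100:400, 5])
  D5_us <- max(s$D[1090:1300, 5])
  D1_us <- max(s$D[1090:1300, 1])
  expect_gt(D5_cs, 2)                       # cue response already present
  expect_gt(D5_us, 0.6 * D1_us)             # reward response barely touched
})

test_that("trained network: cue-evoked D positive, reward D near zero", {
  s <- standard_session()
  lastD <- s$D[, 26:30]
  expect_gt(max(lastD[100:400, ]), 3)
  # convergence: mean |D| integrated over the reward window over the last
  # five trials falls below 20% of its naive (reward-only) value
  us <- us_only_session()
  naive <- mean(colSums(abs(us$D[1050:1300, ])))
  trained <- mean(colSums(abs(lastD[1050:1300, ])))
  expect_lt(trained, 0.2 * naive)
})

test_that("integrated reinforcement transiently exceeds the naive reward bar", {
  s <- standard_session()
  us <- us_only_session()
  baseline <- mean(integrated_da(us))
  curve <- integrated_da(s)
  expect_gt(max(curve), baseline)           # transient excess during training
  expect_lt(mean(curve[26:30]), baseline)   # and it relaxes afterwards
})

test_that("recurrent fixed-point residual shrinks over training", {
  s <- standard_session()
  # |per-trial integral of D| (the traces share the trial's D) acts as the
  # session-level diagnostic: compare the first third to the last third
  resid <- abs(colSums(s$D) * s$dt)
  expect_lt(mean(resid[21:30]), mean(resid[1:10]))
})

test_that("zero learning rates leave the session statistically naive", {
  cfg <- flex_config(plasticity = list(gain_rec = 0, gain_ff = 0,
                                       gain_vta = 0))
  net <- build_flex_network(cfg, seed = 23)
  proto <- trial_protocol(1300, list(stimulus_event("CS1", 100, 100),
                                     stimulus_event("US", 1100, 100)), 4)
  s <- run_session(net, proto, seed = 23)
  w <- s$weight_curves
  expect_true(all(abs(w$mean_weight[w$group == "cs_da:CS1"]) < 1e-12))
  expect_equal(w$mean_weight[w$group == "timer_rec:CS1"],
               rep(flex_config()$network$init_weights$timer_rec, 4))
  # no cue-evoked dopamine develops
  expect_lt(max(s$D[100:400, 4]), 2)
})

test_that("reward omission on a trained network produces the dopamine dip", {
  s <- standard_session()
  om <- cached("omission", reward_omission(s$network, omit_trials = 2,
                                           n_trials = 2, seed = 101,
                                           learn = FALSE))
  expect_lt(min(om$D[1100:1300, 2]), -1)     # dip at expected reward time
  expect_gt(max(om$D[1090:1300, 1]), 1)      # delivered trial still responds
})

test_that("extinction depresses cue weights, gradually and cumulatively", {
  s <- standard_session()
  ext <- cached("extinction", extinction(s$network, n_trials = 10,
                                         seed = 102))
  w <- ext$weight_curves
  cs <- w$mean_weight[w$group == "cs_da:CS1"]
  w0 <- snapshot_weights(s$network)[["cs_da:CS1"]]
  # monotonically non-increasing within noise, and ten trials depress
  # strictly more than one
  expect_lt(cs[10], cs[1])
  expect_lt(abs(w0 - cs[1]), abs(w0 - cs[10]))
  expect_true(all(diff(cs) < 0.02))
})

test_that("messenger peak sits at the expected reward time on a probe trial", {
  p <- standard_probe()
  peak <- messenger_peak_time(p$rates[, "CS1:M", 1])
  expect_lt(abs(peak - 1100), 100)
})
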