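#' Standard trace-conditioning session
#'
#' The basic paradigm: a conditioned stimulus pulse followed, after a silent
#' trace interval, by a reward pulse delivered to the DA population through
#' the fixed gustatory projection.  Over training the Timers' persistent
#' firing grows to span the cue-reward delay, a cue-evoked dopamine response
#' emerges, and the reward-evoked response is suppressed by learned
#' Messenger-driven inhibition.
#'
#' @param net a network built with one column per conditioned stimulus; if
#'   `NULL` a single-column network is built from `config`.
#' @param cs_time,us_time stimulus onsets (ms).
#' @param n_trials training trials.
#' @param trial_length trial duration (ms); defaults to `us_time + 200`.
#' @param seed master seed.
#' @param config configuration used when `net` is `NULL`.
#' @param learn apply plasticity (disable for probe/baseline sessions).
#' @param record_spikes collect spike event tables.
#' @param cs_label which column receives the cue.
#' @return A `flex_session` (see [run_session()]).
#' @export
trace_conditioning <- function(net = NULL, cs_time = 100, us_time = 1100,
                               n_trials = 30, trial_length = us_time + 200,
                               seed = 1, config = flex_config(),
                               learn = TRUE, record_spikes = FALSE,
                               cs_label = "CS1") {
  if (is.null(net)) net <- build_flex_network(config, seed)
  dur <- net$config$stimulus$duration
  proto <- trial_protocol(trial_length, list(
    stimulus_event(cs_label, cs_time, dur),
    stimulus_event("US", us_time, dur)
  ), n_trials)
  run_session(net, proto, seed = seed, learn = learn,
              record_spikes = record_spikes)
}

#' Baseline session (no stimuli)
#'
#' Spontaneous-firing trials used as the reference distribution for the
#' binned auROC analysis and for baseline-rate checks.  Plasticity is off.
#'
#' @param net a built network.
#' @param n_trials number of baseline trials.
#' @param trial_length trial duration (ms).
#' @param seed master seed.
#' @param record_spikes collect spike event tables (on by default; the
#'   purpose of this session is usually spike-count statistics).
#' @return A `flex_session`.
#' @export
baseline_session <- function(net, n_trials = 25, trial_length = 1300,
                             seed = 1, record_spikes = TRUE) {
  proto <- trial_protocol(trial_length, list(), n_trials)
  run_session(net, proto, seed = seed, learn = FALSE,
              record_spikes = record_spikes)
}

#' Reward-omission probe
#'
#' Runs CS+US trials with the US omitted on selected trials.  On omission
#' trials a trained network shows the characteristic dopamine dip: the
#' learned Messenger-driven inhibition arrives at the expected reward time
#' but the excitatory reward drive does not, leaving net inhibition of the
#' DA population and negative D(t) around the expected reward time.
#'
#' @param net a trained network.
#' @param omit_trials indices of trials on which the US is withheld.
#' @param n_trials total trials in the probe session.
#' @param cs_time,us_time stimulus onsets (ms).
#' @param trial_length trial duration (ms).
#' @param seed master seed.
#' @param learn apply plasticity during the probe.
#' @return A `flex_session`.
#' @export
reward_omission <- function(net, omit_trials, n_trials = max(omit_trials),
                            cs_time = 100, us_time = 1100,
                            trial_length = us_time + 200, seed = 1,
                            learn = TRUE) {
  dur <- net$config$stimulus$duration
  proto <- trial_protocol(trial_length, list(
    stimulus_event("CS1", cs_time, dur),
    stimulus_event("US", us_time, dur,
                   trials = setdiff(seq_len(n_trials), omit_trials))
  ), n_trials)
  run_session(net, proto, seed = seed, learn = learn)
}

#' Extinction session
#'
#' CS-only trials on a trained network.  The expected-reward dip produces
#' consistently negative D(t) at the expected reward time, which depresses
#' the CS->DA weights (and unlearns the Messenger->GABA inhibition), driving
#' the cue-evoked dopamine response back toward baseline.
#'
#' @param net a trained network.
#' @param n_trials extinction trials.
#' @param cs_time cue onset (ms).
#' @param trial_length trial duration (ms).
#' @param seed master seed.
#' @return A `flex_session`.
#' @export
extinction <- function(net, n_trials = 20, cs_time = 100,
                       trial_length = 1300, seed = 1) {
  dur <- net$config$stimulus$duration
  proto <- trial_protocol(trial_length,
                          list(stimulus_event("CS1", cs_time, dur)),
                          n_trials)
  run_session(net, proto, seed = seed, learn = TRUE)
}

#' Sequential conditioning session
#'
#' Two cues precede the reward (CS1 -> CS2 -> US), each driving its own
#' cortical column.  Training passes through four stages: initial responses,
#' acquisition of dopamine responses to both cues and the reward, reward
#' suppression, and finally serial transfer of activation to the earliest
#' predictive cue.
#'
#' @param net a two-column network (`columns = c("CS1", "CS2")`); built from
#'   `config` when `NULL`.
#' @param cs1_time,cs2_time,us_time onsets (ms).
#' @param n_trials training trials.
#' @param trial_length trial duration (ms).
#' @param seed master seed.
#' @param config configuration used when `net` is `NULL`.
#' @return A `flex_session`.
#' @export
sequential_conditioning <- function(net = NULL, cs1_time = 100,
                                    cs2_time = 800, us_time = 1500,
                                    n_trials = 80,
                                    trial_length = us_time + 200,
                                    seed = 1, config = NULL) {
  if (is.null(net)) {
    if (is.null(config)) config <- flex_config(
      network = list(columns = c("CS1", "CS2")))
    net <- build_flex_network(config, seed)
  }
  dur <- net$config$stimulus$duration
  proto <- trial_protocol(trial_length, list(
    stimulus_event("CS1", cs1_time, dur),
    stimulus_event("CS2", cs2_time, dur),
    stimulus_event("US", us_time, dur)
  ), n_trials)
  run_session(net, proto, seed = seed, learn = TRUE)
}

#' Blocking / unblocking session
#'
#' A second cue (CS2) is inserted between an already-conditioned CS1 and the
#' reward.  With unchanged reward magnitude the suppressed reward-evoked
#' dopamine provides no reinforcement for the new cue's eligibility traces,
#' so CS2 acquires no dopamine response (blocking).  If the reward magnitude
#' is increased — or exogenous dopamine is injected via `exog_da` — a
#' reward-evoked reinforcement reappears and CS2 conditions (unblocking).
#'
#' @param net a trained two-column network (CS1 conditioned).
#' @param cs1_time,cs2_time,us_time onsets (ms).
#' @param n_trials trials with the inserted cue.
#' @param reward_scale scaling of the US drive magnitude.
#' @param exog_da additive exogenous offset to D(t) (Hz).
#' @param trial_length trial duration (ms).
#' @param seed master seed.
#' @return A `flex_session`.
#' @export
blocking_unblocking <- function(net, cs1_time = 100, cs2_time = 600,
                                us_time = 1100, n_trials = 15,
                                reward_scale = 1, exog_da = 0,
                                trial_length = us_time + 200, seed = 1) {
  dur <- net$config$stimulus$duration
  proto <- trial_protocol(trial_length, list(
    stimulus_event("CS1", cs1_time, dur),
    stimulus_event("CS2", cs2_time, dur),
    stimulus_event("US", us_time, dur, magnitude = reward_scale)
  ), n_trials)
  run_session(net, proto, seed = seed, learn = TRUE, exog_da = exog_da)
}

#' Distractor-robustness experiment
#'
#' Trains a rewarded CS alongside a distractor cue that drives its own
#' column but has no reward contingency, and compares the outcome with a
#' distractor-free run on an identically seeded clean network.  By default
#' distractor pulses fall in the post-reward window during training, so
#' their eligibility traces never overlap reward-evoked reinforcement.
#'
#' @param cs_time,us_time onsets (ms) of the rewarded pair.
#' @param distractor_time distractor onset (ms); the default sits after the
#'   reward-evoked reinforcement has returned to baseline, so the
#'   distractor's eligibility traces never overlap positive D(t) during
#'   their onset transient.
#' @param n_trials training trials.
#' @param trial_length trial duration (ms).
#' @param seed master seed (shared by the paired runs).
#' @param config base configuration; the network gets columns CS1 and DIST.
#' @return List with the two sessions (`with_distractor`, `clean`) and the
#'   final cue-evoked dopamine summary of both.
#' @export
distractor_robustness <- function(cs_time = 100, us_time = 1100,
                                  distractor_time = 1320,
                                  n_trials = 30,
                                  trial_length = us_time + 450,
                                  seed = 1, config = NULL) {
  if (is.null(config)) config <- flex_config(
    network = list(columns = c("CS1", "DIST")))
  dur <- config$stimulus$duration
  net1 <- build_flex_network(config, seed)
  net2 <- build_flex_network(config, seed)
  proto_d <- trial_protocol(trial_length, list(
    stimulus_event("CS1", cs_time, dur),
    stimulus_event("US", us_time, dur),
    stimulus_event("DIST", distractor_time, dur)
  ), n_trials)
  proto_c <- trial_protocol(trial_length, list(
    stimulus_event("CS1", cs_time, dur),
    stimulus_event("US", us_time, dur)
  ), n_trials)
  s_d <- run_session(net1, proto_d, seed = seed)
  s_c <- run_session(net2, proto_c, seed = seed)
  list(with_distractor = s_d, clean = s_c)
}

#' Value-scaling session (neuromodulator variant)
#'
#' Trace conditioning with the non-suppressed neuromodulator A(t) driving
#' the feed-forward CS->DA updates, so the learned cue response scales with
#' the magnitude of the reward drive.
#'
#' @param reward_magnitude scaling of the US drive.
#' @param n_trials training trials.
#' @param cs_time,us_time onsets (ms).
#' @param seed master seed.
#' @param config base configuration (the A-variant flag is forced on).
#' @return A `flex_session` (with the `A` trace populated).
#' @export
value_scaling <- function(reward_magnitude = 1, n_trials = 30,
                          cs_time = 100, us_time = 1100, seed = 1,
                          config = flex_config()) {
  cfg2 <- unclass(config)
  cfg2$plasticity$use_A_variant <- TRUE
  # the variant's fixed point scales with reward value; keep the safety cap
  # well above it so the cap cannot mask the scaling
  cfg2$plasticity$w_max$cs_da <- 4
  cfg2 <- structure(cfg2, class = "flex_config")
  net <- build_flex_network(cfg2, seed)
  dur <- cfg2$stimulus$duration
  proto <- trial_protocol(us_time + 200, list(
    stimulus_event("CS1", cs_time, dur),
    stimulus_event("US", us_time, dur, magnitude = reward_magnitude)
  ), n_trials)
  run_session(net, proto, seed = seed, learn = TRUE)
}
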