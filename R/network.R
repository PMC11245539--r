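#' Build the full FLEX network
#'
#' Assembles the two-region architecture: one cortical feature column per
#' stimulus label — each containing Timer, Inhibitory and Messenger
#' populations of `n_per_pop` LIF neurons — plus a VTA with DA and GABA
#' populations, wired with the fixed connection motif (Timers excite
#' Messengers and the local inhibitory population; the inhibitory population
#' inhibits Messengers; Messengers excite the inhibitory population; GABA
#' inhibits DA) and three classes of plastic projections: recurrent
#' Timer-to-Timer (two-trace rule, cortical variant), stimulus-to-DA
#' feed-forward (two-trace rule, feed-forward variant, sparse), and
#' Messenger-to-GABA (dopamine-modulated Hebbian).  Columns do not interact
#' with each other except through the shared dopamine signal.
#'
#' Construction is deterministic given `seed`: sparse projection masks and
#' the per-synapse feed-forward/VTA learning-rate magnitudes are drawn once
#' here from the build stream.
#'
#' @param cfg a [flex_config()]; `cfg$network$columns` names the feature
#'   columns (one per conditioned stimulus label).
#' @param seed master seed; the builder uses the derived `"build"` stream.
#' @return A list of class `flex_network` with `pops`, `groups`, `config`,
#'   `seed`.
#' @export
build_flex_network <- function(cfg = flex_config(), seed = 1) {
  stopifnot(inherits(cfg, "flex_config"))
  set.seed(child_seed(seed, "build"))
  n <- cfg$neuron$n_per_pop
  fw <- cfg$network$fixed_weights
  pl <- cfg$plasticity
  delay <- cfg$sim$delay_ms
  intra <- cfg$sim$intra_delay_ms
  sp <- cfg$network$projection_sparsity

  pops <- list()
  groups <- list()
  add_group <- function(g) groups[[length(groups) + 1L]] <<- g

  mk_pop <- function(type, s_classes, noise_mean = 0, noise_sd = 0) {
    p <- population_params(n, type, s_classes, noise_mean, noise_sd, cfg)
    list(params = p, state = population_state(p), stim = FALSE)
  }
  mk_stim <- function(s_classes) {
    p <- population_params(cfg$stimulus$n_units, "E", s_classes,
                           cfg = cfg)
    list(params = p, state = population_state(p), stim = TRUE)
  }

  # VTA
  pops$DA <- mk_pop("E", "VTAe", cfg$noise$tonic_da, cfg$noise$vta_sd)
  pops$GABA <- mk_pop("I", "VTAi", cfg$noise$tonic_gaba, cfg$noise$vta_sd)
  add_group(connection_group("GABA", "DA", fw$gaba_da, sign = -1,
                             s_class = "VTAi", delay_ms = delay,
                             n_pre = n, n_post = n))

  # US channel: fixed sparse gustatory projection onto DA neurons
  pops[["stim:US"]] <- mk_stim("VTAe")
  us_mask <- matrix(stats::rbinom(n * cfg$stimulus$n_units, 1, sp),
                    n, cfg$stimulus$n_units)
  add_group(connection_group("stim:US", "DA", fw$us_da * us_mask, sign = 1,
                             s_class = "VTAe", delay_ms = delay))

  # cortical feature columns
  for (lab in cfg$network$columns) {
    Tn <- paste0(lab, ":T"); In <- paste0(lab, ":I"); Mn <- paste0(lab, ":M")
    pops[[Tn]] <- mk_pop("E", "E", 0, cfg$noise$pfc_sd)
    pops[[In]] <- mk_pop("I", "I", cfg$noise$tonic_i)
    pops[[Mn]] <- mk_pop("E", c("E", "VTAe"), 0, cfg$noise$pfc_sd)
    pops[[paste0("stim:", lab)]] <- mk_stim(c("E", "VTAe"))

    # plastic recurrent Timer->Timer
    add_group(connection_group(
      Tn, Tn, cfg$network$init_weights$timer_rec, sign = 1, s_class = "E",
      delay_ms = intra, n_pre = n, n_post = n,
      plasticity = list(rule = "dttl", region = "PFC",
                        elig = eligibility_state(n, n, "recurrent", cfg),
                        eta = pl$eta_rec * pl$gain_rec,
                        w_max = pl$w_max$timer_rec)))
    # fixed intracolumn motif
    add_group(connection_group(Tn, Mn, fw$t_m, sign = 1, s_class = "E",
                               delay_ms = delay, n_pre = n, n_post = n))
    add_group(connection_group(Tn, In, fw$t_i, sign = 1, s_class = "E",
                               delay_ms = delay, n_pre = n, n_post = n))
    add_group(connection_group(Mn, In, fw$m_i, sign = 1, s_class = "E",
                               delay_ms = delay, n_pre = n, n_post = n))
    add_group(connection_group(In, Mn, fw$i_m, sign = -1, s_class = "I",
                               delay_ms = delay, n_pre = n, n_post = n))
    # fixed stimulus drive onto the column's Timers
    add_group(connection_group(paste0("stim:", lab), Tn, fw$cs_t, sign = 1,
                               s_class = "E", delay_ms = delay,
                               n_pre = cfg$stimulus$n_units, n_post = n))
    # feed-forward inhibition: the stimulus also recruits the column's
    # inhibitory population, keeping Messengers silent at cue onset
    add_group(connection_group(paste0("stim:", lab), In, fw$cs_i, sign = 1,
                               s_class = "E", delay_ms = delay,
                               n_pre = cfg$stimulus$n_units, n_post = n))
    # plastic feed-forward CS->DA (sparse substrate)
    cs_mask <- matrix(stats::rbinom(n * cfg$stimulus$n_units, 1, sp),
                      n, cfg$stimulus$n_units)
    eta_ff <- abs(stats::rnorm(n * cfg$stimulus$n_units, 0, pl$eta_ff_sd)) *
      pl$gain_ff * cs_mask
    W0 <- matrix(cfg$network$init_weights$cs_da, n, cfg$stimulus$n_units) *
      cs_mask
    add_group(connection_group(
      paste0("stim:", lab), "DA", W0, sign = 1, s_class = "VTAe",
      delay_ms = delay,
      plasticity = list(rule = "dttl", region = "VTA",
                        elig = eligibility_state(n, cfg$stimulus$n_units,
                                                 "feedforward", cfg),
                        eta = matrix(eta_ff, n, cfg$stimulus$n_units),
                        mask = cs_mask,
                        use_A = isTRUE(pl$use_A_variant),
                        w_max = pl$w_max$cs_da)))
    # plastic Messenger->GABA
    eta_vta <- abs(stats::rnorm(n * n, 0, pl$eta_vta_sd)) * pl$gain_vta
    add_group(connection_group(
      Mn, "GABA", cfg$network$init_weights$m_gaba, sign = 1,
      s_class = "VTAe", delay_ms = delay, n_pre = n, n_post = n,
      plasticity = if (isTRUE(pl$m_gaba_dttl)) {
        list(rule = "dttl", region = "VTA",
             elig = eligibility_state(n, n, "feedforward", cfg),
             eta = matrix(eta_vta, n, n), w_max = pl$w_max$m_gaba)
      } else {
        list(rule = "da_hebb", region = "VTA",
             eta = matrix(eta_vta, n, n), w_max = pl$w_max$m_gaba)
      }))
  }

  # shadow DA population for the value-tracking neuromodulator A(t):
  # receives the same feed-forward drive as DA but sees only the tonic
  # (unlearned) level of GABA inhibition
  if (isTRUE(pl$use_A_variant)) {
    pops$DA_shadow <- mk_pop("E", "VTAe", cfg$noise$tonic_da,
                             cfg$noise$vta_sd)
  }

  structure(list(config = cfg, seed = seed, pops = pops, groups = groups),
            class = "flex_network")
}

#' @export
print.flex_network <- function(x, ...) {
  np <- names(x$pops)
  cat("flex_network:", sum(!startsWith(np, "stim:")), "populations,",
      length(x$groups), "connection groups\n")
  cat("  columns:", paste(x$config$network$columns, collapse = ", "), "\n")
  w <- snapshot_weights(x)
  cat("  mean plastic weights:",
      paste(sprintf("%s=%.4g", names(w), w), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a Poisson stimulus pulse
#'
#' Independent Bernoulli spikes at the pulse rate for every stimulus unit in
#' every timestep of `[onset, onset + duration)`.  Uses R's global RNG.
#'
#' @param event a [stimulus_event()].
#' @param dt timestep (ms).
#' @param steps total number of steps in the trial.
#' @param n_units number of stimulus units.
#' @return Logical matrix (`steps` x `n_units`).
#' @export
make_poisson_stimulus <- function(event, dt, steps, n_units = 100) {
  spk <- matrix(FALSE, steps, n_units)
  if (event$duration <= 0 || event$rate <= 0) return(spk)
  i0 <- floor(event$onset / dt) + 1L
  i1 <- min(ceiling((event$onset + event$duration) / dt), steps)
  if (i1 < i0) return(spk)
  p <- min(event$rate * dt / 1000, 1)
  nwin <- i1 - i0 + 1L
  spk[i0:i1, ] <- matrix(stats::runif(nwin * n_units) < p, nwin, n_units)
  spk
}

#' Describe a stimulus presentation
#'
#' @param label stimulus identity, matching a network column (`"CS1"`, ...)
#'   or `"US"`.
#' @param onset onset time within the trial (ms).
#' @param duration pulse width (ms).
#' @param rate Poisson pulse rate (Hz).
#' @param magnitude scaling of the fixed projection drive (used for reward
#'   value and unblocking protocols).
#' @param trials integer vector of trial indices on which the event is
#'   delivered, or `NULL` for every trial.
#' @return A list of class `stimulus_event`.
#' @export
stimulus_event <- function(label, onset, duration = 100, rate = 30,
                           magnitude = 1, trials = NULL) {
  stopifnot(onset >= 0, duration >= 0, rate >= 0, magnitude >= 0)
  structure(list(label = label, onset = onset, duration = duration,
                 rate = rate, magnitude = magnitude, trials = trials),
            class = "stimulus_event")
}

#' Define a trial protocol
#'
#' @param trial_length trial duration (ms).
#' @param events list of [stimulus_event()]s.
#' @param n_trials number of trials.
#' @return List of class `trial_protocol`.
#' @export
trial_protocol <- function(trial_length, events, n_trials) {
  stopifnot(n_trials >= 1, trial_length > 0)
  for (ev in events) {
    if (ev$onset + ev$duration > trial_length) {
      stop("event '", ev$label, "' extends past the trial end",
           call. = FALSE)
    }
  }
  structure(list(trial_length = trial_length, events = events,
                 n_trials = as.integer(n_trials)),
            class = "trial_protocol")
}

#' Mean plastic weights of the network
#'
#' Returns the mean weight of each plastic group (over the existing synapses
#' for sparse groups): the three learning curves usually plotted over
#' training are the Timer->Timer, CS->DA and Messenger->GABA means.
#'
#' @param net a [build_flex_network()] object.
#' @return Named numeric vector.
#' @export
snapshot_weights <- function(net) {
  out <- stats::setNames(numeric(0), character(0))
  for (g in net$groups) {
    if (is.null(g$plasticity)) next
    mask <- g$plasticity$mask
    w <- if (is.null(mask)) mean(g$W) else mean(g$W[mask == 1])
    nm <- if (g$pre == g$post) {
      paste0("timer_rec:", sub(":T$", "", g$pre))
    } else if (startsWith(g$pre, "stim:")) {
      paste0("cs_da:", sub("^stim:", "", g$pre))
    } else {
      paste0("m_gaba:", sub(":M$", "", g$pre))
    }
    out[nm] <- w
  }
  out
}

#' Measure the unstimulated VTA baseline firing rate
#'
#' Runs the network with no stimuli and plasticity off for `duration_ms` and
#' returns the mean firing rate of the DA and GABA populations (spike count
#' over time), the quantity the tonic drive is calibrated against.
#'
#' @param net a `flex_network` (a VTA-only network is sufficient).
#' @param duration_ms measurement window (ms).
#' @param seed seed for the measurement noise stream.
#' @return Named vector with elements `DA`, `GABA` and `VTA` (pooled), Hz.
#' @export
vta_baseline_rate <- function(net, duration_ms = 10000, seed = 1) {
  set.seed(child_seed(seed, "baseline"))
  out <- run_trial(net, events = list(), trial_length = duration_ms,
                   learn = FALSE, record_spikes = FALSE)
  counts <- out$rec$spike_counts
  rate <- function(pop) sum(counts[[pop]]) / (duration_ms / 1000) /
    net$pops[[pop]]$params$n
  c(DA = rate("DA"), GABA = rate("GABA"),
    VTA = (sum(counts$DA) + sum(counts$GABA)) /
      (duration_ms / 1000) / (2 * net$pops$DA$params$n))
}

#' Calibrate the tonic VTA drive to the target baseline rate
#'
#' Bisection on the constant drive current so that the unstimulated GABA and
#' DA populations fire at the target baseline (~5 Hz).  GABA is calibrated
#' first (it receives no synaptic input at rest), then DA under the
#' resulting GABA inhibitory tone.
#'
#' @param cfg a [flex_config()].
#' @param seed seed for the calibration noise stream.
#' @param target target rate (Hz).
#' @param tol acceptable deviation (Hz).
#' @param window_ms simulation window per bisection evaluation (ms).
#' @param max_iter bisection iterations per population.
#' @return The configuration with updated `noise$tonic_da` /
#'   `noise$tonic_gaba`, with the achieved rates in attribute
#'   `"achieved_rates"`.
#' @export
calibrate_baseline <- function(cfg = flex_config(), seed = 1, target = 5,
                               tol = 0.25, window_ms = 4000, max_iter = 9) {
  vta_cfg <- function(cfg) {
    cfg2 <- unclass(cfg)
    cfg2$network$columns <- character(0)
    structure(cfg2, class = "flex_config")
  }
  measure <- function(cfg, it) {
    net <- build_flex_network(vta_cfg(cfg), seed = seed)
    vta_baseline_rate(net, window_ms, seed = seed + it)
  }
  bisect <- function(cfg, key, pop, lo = 0, hi = 250) {
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      cfg$noise[[key]] <- mid
      r <- measure(cfg, it)[[pop]]
      if (abs(r - target) <= tol) break
      if (r > target) hi <- mid else lo <- mid
    }
    cfg
  }
  cfg <- bisect(cfg, "tonic_gaba", "GABA")
  cfg <- bisect(cfg, "tonic_da", "DA")
  final <- measure(cfg, 0)
  attr(cfg, "achieved_rates") <- final
  cfg
}
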