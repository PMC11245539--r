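#' Simulate one trial
#'
#' Advances the whole network for one trial at the configured timestep,
#' applying plasticity online.  Membrane, synaptic, rate and eligibility
#' state are initialised fresh (trials are analysed independently and traces
#' do not outlive the inter-trial interval); synaptic weights carry over and
#' are modified in place by learning.  A short unrecorded warm-up period is
#' simulated first so that tonic firing and the rate estimators have settled
#' when the recorded window starts.
#'
#' The caller controls the RNG seed (see [run_session()]); given identical
#' weights, events and seed the trial is fully reproducible.
#'
#' @param net a [build_flex_network()] object.
#' @param events list of [stimulus_event()]s for this trial (already
#'   filtered to the ones active on this trial).
#' @param trial_length trial duration (ms).
#' @param learn apply plasticity?
#' @param record_spikes collect the per-neuron spike event table?
#' @param warmup_ms unrecorded settling time before t = 0.
#' @param exog_da additive exogenous offset to D(t) (Hz), used by the
#'   unblocking protocol.
#' @return List with the updated `net` and a recording fragment `rec`
#'   containing `rates` (steps x populations, Hz), `D`, `A` (if the value
#'   variant is enabled), `spike_counts` (one neurons-vector per
#'   population), `spikes` (event data frame if requested) and `weights`
#'   (snapshot after the trial).
#' @export
run_trial <- function(net, events, trial_length, learn = TRUE,
                      record_spikes = FALSE, warmup_ms = 200, exog_da = 0) {
  cfg <- net$config
  dt <- cfg$sim$dt
  steps <- round(trial_length / dt)
  wsteps <- round(warmup_ms / dt)
  total <- steps + wsteps
  pl <- cfg$plasticity
  use_A <- isTRUE(pl$use_A_variant)
  pops <- net$pops
  groups <- net$groups
  pnames <- names(pops)

  # reset per-trial state; VTA rate estimators start at the tonic baseline
  for (nm in pnames) {
    pops[[nm]]$state <- population_state(pops[[nm]]$params)
    if (nm %in% c("DA", "GABA", "DA_shadow")) {
      pops[[nm]]$state$r <- rep(pl$d0, pops[[nm]]$params$n)
    }
  }

  # stimulus spike trains and per-trial drive magnitudes
  stim_mag <- list()
  stim_spk <- list()
  for (nm in pnames[startsWith(pnames, "stim:")]) {
    lab <- sub("^stim:", "", nm)
    nunits <- pops[[nm]]$params$n
    spk <- matrix(FALSE, total, nunits)
    mag <- 1
    for (ev in events) {
      if (ev$label != lab) next
      m <- make_poisson_stimulus(ev, dt, steps, nunits)
      spk[(wsteps + 1):total, ] <- spk[(wsteps + 1):total, ] | m
      mag <- ev$magnitude
    }
    stim_spk[[nm]] <- spk
    stim_mag[[nm]] <- mag
  }

  # delay ring buffers for synaptic activations, one per population/class
  nring <- max(vapply(groups, function(g) g$delay_ms, 0)) / dt + 1
  sbuf <- lapply(pops, function(p) {
    lapply(p$state$s, function(s) matrix(0, length(s), nring))
  })
  slot <- function(t) ((t - 1) %% nring) + 1

  # precompiled group lookups
  g_pre <- vapply(groups, `[[`, "", "pre")
  g_post <- vapply(groups, `[[`, "", "post")
  g_class <- vapply(groups, `[[`, "", "s_class")
  g_delay <- vapply(groups, function(g) g$delay_ms / dt, 0)
  g_plastic <- which(vapply(groups, function(g) !is.null(g$plasticity),
                            NA))

  rec_pops <- pnames[!startsWith(pnames, "stim:")]
  rates <- matrix(0, steps, length(rec_pops),
                  dimnames = list(NULL, rec_pops))
  D_tr <- numeric(steps)
  A_tr <- if (use_A) numeric(steps) else NULL
  counts <- lapply(pops[rec_pops], function(p) integer(p$params$n))
  spk_events <- if (record_spikes) vector("list", steps) else NULL

  gaba_tone <- NULL  # fixed inhibitory conductance seen by the shadow DA
  if (use_A) {
    nb <- cfg$neuron
    r0 <- pl$d0 / 1000
    s_bar <- nb$rho * r0 * nb$tau_s$VTAi / (1 + nb$rho * r0 * nb$tau_s$VTAi)
    gaba_tone <- abs(cfg$network$fixed_weights$gaba_da) *
      cfg$neuron$n_per_pop * s_bar
  }

  D_t <- 0
  A_t <- 0
  for (t in seq_len(total)) {
    recording <- t > wsteps
    ti <- t - wsteps

    # conductance accumulation from delayed activations
    g_E <- lapply(pops, function(p) numeric(p$params$n))
    g_I <- g_E
    for (k in seq_along(groups)) {
      src <- t - g_delay[k]
      s_pre <- sbuf[[g_pre[k]]][[g_class[k]]][, slot(src)]
      mag <- stim_mag[[g_pre[k]]]
      g <- conductance(groups[[k]], s_pre)
      if (!is.null(mag) && mag != 1) g <- g * mag
      if (groups[[k]]$sign > 0) {
        g_E[[g_post[k]]] <- g_E[[g_post[k]]] + g
      } else {
        g_I[[g_post[k]]] <- g_I[[g_post[k]]] + g
      }
    }
    if (use_A) {
      # shadow DA: same excitatory drive as DA, tonic-level inhibition only
      g_E$DA_shadow <- g_E$DA
      g_I$DA_shadow <- rep(gaba_tone, pops$DA_shadow$params$n)
    }

    # advance neurons / stimulus units
    for (nm in pnames) {
      p <- pops[[nm]]
      if (p$stim) {
        p$state$spikes <- stim_spk[[nm]][t, ]
      } else {
        p$state <- step_membrane(p$state, p$params, g_E[[nm]], g_I[[nm]],
                                 dt)
      }
      p$state <- update_synaptic_activation(p$state, p$params, dt)
      p$state$r <- estimate_rates(p$state$r, p$state$spikes,
                                  p$params$tau_r, dt)
      for (cl in names(p$state$s)) {
        sbuf[[nm]][[cl]][, slot(t)] <- p$state$s[[cl]]
      }
      pops[[nm]] <- p
    }

    D_t <- dopamine_signal(mean(pops$DA$state$r), pl$d0, pl$theta) + exog_da
    if (use_A) {
      A_t <- dopamine_signal(mean(pops$DA_shadow$state$r), pl$d0, pl$theta)
    }

    # online plasticity
    if (learn && recording) {
      for (k in g_plastic) {
        g <- groups[[k]]
        p <- g$plasticity
        r_pre <- pops[[g$pre]]$state$r / pl$hebb_rate_scale
        r_post <- pops[[g$post]]$state$r / pl$hebb_rate_scale
        if (p$rule == "dttl") {
          H <- hebbian_coincidence(r_pre, r_post, p$region, D_t,
                                   pl$alpha_pfc, pl$pfc_floor)
          p$elig <- update_eligibility(p$elig, H, dt)
          drive <- if (isTRUE(p$use_A)) A_t else D_t
          g$W <- dttl_weight_update(g$W, drive, p$elig$T_p, p$elig$T_d,
                                    p$eta, dt, p$w_max)
        } else {
          g$W <- da_hebbian_update(g$W, D_t, r_pre, r_post, p$eta, dt,
                                   p$w_max)
        }
        g$plasticity <- p
        groups[[k]] <- g
      }
    }

    if (recording) {
      for (nm in rec_pops) {
        st <- pops[[nm]]$state
        rates[ti, nm] <- mean(st$r)
        if (any(st$spikes)) {
          idx <- which(st$spikes)
          counts[[nm]][idx] <- counts[[nm]][idx] + 1L
          if (record_spikes) {
            spk_events[[ti]] <- rbind(
              spk_events[[ti]],
              cbind(time = ti * dt, pop = match(nm, rec_pops),
                    neuron = idx))
          }
        }
      }
      D_tr[ti] <- D_t
      if (use_A) A_tr[ti] <- A_t
    }
  }

  # strip per-trial eligibility state (reset at trial boundaries)
  for (k in g_plastic) {
    p <- groups[[k]]$plasticity
    if (!is.null(p$elig)) {
      p$elig$T_p[] <- 0
      p$elig$T_d[] <- 0
      groups[[k]]$plasticity <- p
    }
  }
  net$pops <- pops
  net$groups <- groups

  spikes <- NULL
  if (record_spikes) {
    m <- do.call(rbind, spk_events)
    spikes <- if (is.null(m)) {
      data.frame(time_ms = numeric(0), population = character(0),
                 neuron_id = integer(0))
    } else {
      data.frame(time_ms = m[, "time"],
                 population = rec_pops[m[, "pop"]],
                 neuron_id = as.integer(m[, "neuron"]))
    }
  }
  list(net = net,
       rec = list(rates = rates, D = D_tr, A = A_tr,
                  spike_counts = counts, spikes = spikes,
                  weights = snapshot_weights(net)))
}

#' Run a full session of a protocol
#'
#' Executes `protocol$n_trials` trials of a [trial_protocol()] on a network,
#' with per-trial seeding derived from the master seed so that sessions are
#' bit-reproducible and individual trials can be re-simulated in isolation.
#'
#' @param net a [build_flex_network()] object.
#' @param protocol a [trial_protocol()].
#' @param seed master seed for the session's stimulus/noise streams.
#' @param learn apply plasticity?
#' @param record_spikes collect spike event tables?
#' @param exog_da additive exogenous offset to D(t) (Hz).
#' @param warmup_ms unrecorded settling time per trial (ms).
#' @return A list of class `flex_session`: `rates` (steps x populations x
#'   trials), `D` and optionally `A` (steps x trials), `weight_curves`
#'   (data frame of per-trial mean plastic weights), `spike_counts` (list of
#'   neurons x trials matrices per population), `spikes` (event table with a
#'   trial column, if recorded), `network` (the trained network), `protocol`,
#'   `seed` and `config_hash`.
#' @export
run_session <- function(net, protocol, seed = 1, learn = TRUE,
                        record_spikes = FALSE, exog_da = 0,
                        warmup_ms = 200) {
  stopifnot(inherits(protocol, "trial_protocol"))
  nt <- protocol$n_trials
  steps <- round(protocol$trial_length / net$config$sim$dt)
  rec_pops <- names(net$pops)[!startsWith(names(net$pops), "stim:")]
  rates <- array(0, c(steps, length(rec_pops), nt),
                 dimnames = list(NULL, rec_pops, NULL))
  D <- matrix(0, steps, nt)
  A <- if (isTRUE(net$config$plasticity$use_A_variant)) {
    matrix(0, steps, nt)
  } else NULL
  counts <- lapply(net$pops[rec_pops],
                   function(p) matrix(0L, p$params$n, nt))
  wlist <- vector("list", nt)
  spk <- if (record_spikes) vector("list", nt) else NULL

  for (i in seq_len(nt)) {
    evs <- Filter(function(ev) is.null(ev$trials) || i %in% ev$trials,
                  protocol$events)
    set.seed(child_seed(seed, paste0("trial:", i)))
    out <- run_trial(net, evs, protocol$trial_length, learn = learn,
                     record_spikes = record_spikes, warmup_ms = warmup_ms,
                     exog_da = exog_da)
    net <- out$net
    rates[, , i] <- out$rec$rates
    D[, i] <- out$rec$D
    if (!is.null(A)) A[, i] <- out$rec$A
    for (nm in rec_pops) counts[[nm]][, i] <- out$rec$spike_counts[[nm]]
    wlist[[i]] <- out$rec$weights
    if (record_spikes) {
      s <- out$rec$spikes
      if (nrow(s)) s$trial <- i
      spk[[i]] <- s
    }
  }

  weight_curves <- do.call(rbind, lapply(seq_len(nt), function(i) {
    data.frame(trial = rep(i, length(wlist[[i]])),
               group = names(wlist[[i]]) %||% character(0),
               mean_weight = unname(wlist[[i]]), row.names = NULL)
  }))
  spikes <- if (record_spikes) do.call(rbind, spk) else NULL
  structure(list(rates = rates, D = D, A = A, spike_counts = counts,
                 weight_curves = weight_curves, spikes = spikes,
                 network = net, protocol = protocol, seed = seed,
                 dt = net$config$sim$dt,
                 config_hash = config_hash(net$config)),
            class = "flex_session")
}

#' @export
print.flex_session <- function(x, ...) {
  cat("flex_session:", dim(x$rates)[3], "trials of",
      x$protocol$trial_length, "ms\n")
  cat("  populations:", paste(dimnames(x$rates)[[2]], collapse = ", "),
      "\n")
  cat("  per-trial integrated D(t):",
      paste(sprintf("%.1f", utils::head(integrated_da(x), 5)),
            collapse = ", "),
      if (dim(x$rates)[3] > 5) "..." else "", "\n")
  invisible(x)
}
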