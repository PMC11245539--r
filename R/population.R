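#' Construct parameters for a leaky integrate-and-fire population
#'
#' @param n number of neurons.
#' @param type `"E"` or `"I"`; selects the spike threshold (-55 mV for
#'   excitatory, -50 mV for inhibitory neurons).
#' @param s_classes character vector of synaptic-activation classes this
#'   population projects through (keys of `cfg$neuron$tau_s`).  A population
#'   keeps one activation variable per class because the activation time
#'   constant is a property of the connection class, not of the neuron.
#' @param noise_mean,noise_sd tonic drive (pA) and white-noise std (pA).
#' @param cfg a [flex_config()] object supplying the shared constants.
#' @return A list of class `population_params`.
#' @export
population_params <- function(n, type = c("E", "I"), s_classes = "E",
                              noise_mean = 0, noise_sd = 0,
                              cfg = flex_config()) {
  type <- match.arg(type)
  nb <- cfg$neuron
  stopifnot(n >= 1, all(s_classes %in% names(nb$tau_s)))
  structure(list(
    n = as.integer(n), type = type,
    C_m = nb$C_m, g_L = nb$g_L,
    E_L = nb$E_L, E_E = nb$E_E, E_I = nb$E_I,
    v_th = if (type == "E") nb$v_th_E else nb$v_th_I,
    v_hold = nb$v_hold, v_rest = nb$v_rest,
    t_ref = nb$t_ref, rho = nb$rho, tau_r = nb$tau_r,
    tau_s = unlist(nb$tau_s[s_classes]),
    noise_mean = noise_mean, noise_sd = noise_sd
  ), class = "population_params")
}

#' Construct the evolving state of a population
#'
#' Membrane potentials start at the resting potential, synaptic activations
#' and rate estimates at zero, with no neuron refractory.
#'
#' @param params a [population_params()] object.
#' @return A list of class `population_state` with elements `v`, `s`
#'   (one numeric vector per synaptic class), `refrac`, `spikes` and `r`.
#' @export
population_state <- function(params) {
  n <- params$n
  structure(list(
    v = rep(params$v_rest, n),
    s = lapply(params$tau_s, function(tau) numeric(n)),
    refrac = numeric(n),
    spikes = logical(n),
    r = numeric(n)
  ), class = "population_state")
}

#' One membrane integration step
#'
#' Integrates `C dv/dt = g_L (E_L - v) + g_E (E_E - v) + g_I (E_I - v) + I`
#' for one timestep by exponential integration conditional on the current
#' conductances: `v <- v_inf + (v - v_inf) exp(-g_tot dt / C)` with
#' `v_inf = (g_L E_L + g_E E_E + g_I E_I + I) / g_tot`.  This is exact for
#' piecewise-constant conductances, reduces to the leak closed form when all
#' synaptic input is zero, and remains stable for the very large inhibitory
#' conductances the network generates (where a plain Euler step at 1 ms
#' would oscillate).  Neurons crossing their threshold emit a spike, are
#' reset to the holding potential and become refractory; refractory neurons
#' are held at the holding potential and cannot spike.  The noise term is an
#' additive white-noise current with std `params$noise_sd` (pA), applied as
#' a `sqrt(dt)`-scaled voltage kick, drawn from R's global RNG (seed it for
#' reproducibility).
#'
#' @param state a [population_state()].
#' @param params a [population_params()].
#' @param g_E,g_I excitatory/inhibitory conductance per neuron (nS, scalar or
#'   length-`n`); must be non-negative.
#' @param dt timestep (ms).
#' @param noise logical; set `FALSE` to suppress the stochastic term even if
#'   `noise_sd > 0` (the tonic mean drive is still applied).
#' @return The updated `population_state` with `spikes` marking this step's
#'   spikes.
#' @export
step_membrane <- function(state, params, g_E = 0, g_I = 0, dt = 1,
                          noise = TRUE) {
  n <- params$n
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (length(state$v) != n) {
    stop("state dimension (", length(state$v),
         ") does not match params$n (", n, ")", call. = FALSE)
  }
  if (!(length(g_E) %in% c(1L, n)) || !(length(g_I) %in% c(1L, n))) {
    stop("conductance vectors must have length 1 or n", call. = FALSE)
  }
  if (any(g_E < 0) || any(g_I < 0)) {
    stop("conductances must be non-negative", call. = FALSE)
  }
  v <- state$v
  g_tot <- params$g_L + g_E + g_I
  v_inf <- (params$g_L * params$E_L + g_E * params$E_E +
              g_I * params$E_I + params$noise_mean) / g_tot
  v_new <- v_inf + (v - v_inf) * exp(-g_tot * dt / params$C_m)
  if (noise && params$noise_sd > 0) {
    v_new <- v_new +
      stats::rnorm(n, 0, params$noise_sd) * sqrt(dt) / params$C_m
  }
  in_ref <- state$refrac > 0
  v <- ifelse(in_ref, params$v_hold, v_new)
  if (any(!is.finite(v))) {
    stop("numerical instability: non-finite membrane potential at neuron ",
         which(!is.finite(v))[1], call. = FALSE)
  }
  spikes <- !in_ref & (v >= params$v_th)
  v[spikes] <- params$v_hold
  refrac <- pmax(state$refrac - dt, 0)
  refrac[spikes] <- params$t_ref
  state$v <- v
  state$spikes <- spikes
  state$refrac <- refrac
  state
}

#' Update saturating synaptic activations
#'
#' Each activation class decays exponentially with its own time constant and,
#' on a spike of neuron i, increments by `rho * (1 - s_i)`, which confines
#' `s` to `[0, 1]` for any spike train.
#'
#' @param state a [population_state()] whose `spikes` field marks the current
#'   step's spikes.
#' @param params a [population_params()].
#' @param dt timestep (ms).
#' @return The updated state.
#' @export
update_synaptic_activation <- function(state, params, dt = 1) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  spk <- state$spikes
  for (cl in names(state$s)) {
    s <- state$s[[cl]] * exp(-dt / params$tau_s[[cl]])
    if (any(spk)) s[spk] <- s[spk] + params$rho * (1 - s[spk])
    state$s[[cl]] <- s
  }
  state
}

#' Exponential firing-rate estimate
#'
#' Implements `tau_r dr/dt = -r + sum_k delta(t - t_k)`: the estimate decays
#' with `tau_r` and jumps by `1000 / tau_r` on each spike so that `r` is in
#' Hz.  A sustained Poisson train at rate f yields a time-averaged estimate
#' of f.
#'
#' @param r current rate estimates (Hz).
#' @param spikes logical (or 0/1) spike indicator for this step.
#' @param tau_r rate time constant (ms).
#' @param dt timestep (ms).
#' @return Updated rate vector (Hz).
#' @export
estimate_rates <- function(r, spikes, tau_r, dt = 1) {
  r * exp(-dt / tau_r) + as.numeric(spikes) * (1000 / tau_r)
}

#' Filter a full spike history into rate estimates
#'
#' Convenience wrapper applying [estimate_rates()] along a (steps x neurons)
#' 0/1 spike matrix, returning the matrix of rate estimates (Hz).
#'
#' @param spike_history matrix, steps in rows, neurons in columns.
#' @param tau_r rate time constant (ms).
#' @param dt timestep (ms).
#' @return Matrix of the same shape with the running rate estimate.
#' @export
rate_history <- function(spike_history, tau_r, dt = 1) {
  spike_history <- as.matrix(spike_history)
  out <- matrix(0, nrow(spike_history), ncol(spike_history))
  r <- numeric(ncol(spike_history))
  for (t in seq_len(nrow(spike_history))) {
    r <- estimate_rates(r, spike_history[t, ], tau_r, dt)
    out[t, ] <- r
  }
  out
}
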