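#' Signed dopaminergic reinforcement signal
#'
#' Maps the population-mean DA firing rate onto the signed reinforcement
#' D(t): zero inside the neutral band `(r0 - theta, r0 + theta)` and linear
#' in the excursion beyond either edge, so the signal is continuous at both
#' edges and can be positive (burst) or negative (pause).
#'
#' @param r_da DA population rate (Hz); scalar or vector, must be >= 0.
#' @param r0 baseline rate (Hz).
#' @param theta neutral half-width (Hz).
#' @return Signed reinforcement (Hz), same length as `r_da`.
#' @export
#' @examples
#' dopamine_signal(c(2, 5, 7, 10))   # -1, 0, 0, 3
dopamine_signal <- function(r_da, r0 = 5, theta = 2) {
  if (any(r_da < 0)) stop("firing rates must be non-negative", call. = FALSE)
  lo <- r0 - theta
  hi <- r0 + theta
  ifelse(r_da <= lo, r_da - lo, ifelse(r_da >= hi, r_da - hi, 0))
}

#' Hebbian coincidence term
#'
#' The per-synapse Hebbian drive is the product of pre- and postsynaptic
#' rate estimates (given here in spikes/ms).  In VTA the product is used
#' directly; in PFC it is divided by `1 + alpha * D(t)`, which restricts
#' cortical trace generation during large positive reinforcement.  The
#' divisor is clamped from below so that strongly negative D cannot flip or
#' blow up the sign of the term, keeping H >= 0.
#'
#' @param r_pre presynaptic rates (spikes/ms), length `n_pre`.
#' @param r_post postsynaptic rates (spikes/ms), length `n_post`.
#' @param region `"VTA"` or `"PFC"`.
#' @param D current signed reinforcement (Hz); only used for PFC.
#' @param alpha suppression coefficient (1/Hz).
#' @param floor lower clamp of the divisor.
#' @return `n_post` x `n_pre` matrix of Hebbian products.
#' @export
hebbian_coincidence <- function(r_pre, r_post, region = c("VTA", "PFC"),
                                D = 0, alpha = 1, floor = 0.1) {
  region <- match.arg(region)
  if (any(r_pre < 0) || any(r_post < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  H <- outer(r_post, r_pre)
  if (region == "PFC") H <- H / max(1 + alpha * D, floor)
  H
}

#' Eligibility-trace state for a plastic pathway
#'
#' Each synapse carries one potentiation-associated (LTP) and one
#' depression-associated (LTD) trace.  Both are activated by the Hebbian
#' term, saturate at their ceiling and decay with their own time constant;
#' the published recurrent and feed-forward parameter sets differ in all six
#' constants.
#'
#' @param n_post,n_pre matrix dimensions.
#' @param variant `"recurrent"` or `"feedforward"`, selecting the default
#'   parameter set from `cfg`.
#' @param cfg a [flex_config()].
#' @return List of class `eligibility_state` with matrices `T_p`, `T_d` and
#'   the parameter set.
#' @export
eligibility_state <- function(n_post, n_pre,
                              variant = c("recurrent", "feedforward"),
                              cfg = flex_config()) {
  variant <- match.arg(variant)
  p <- cfg$plasticity[[variant]]
  structure(list(
    T_p = matrix(0, n_post, n_pre),
    T_d = matrix(0, n_post, n_pre),
    tau_p = p$tau_p, tau_d = p$tau_d,
    eta_p = p$eta_p, eta_d = p$eta_d,
    T_max_p = p$T_max_p, T_max_d = p$T_max_d,
    variant = variant
  ), class = "eligibility_state")
}

#' Advance the two eligibility traces by one step
#'
#' Forward-Euler update of
#' `tau_a dT_a/dt = -T_a + eta_a * H * (T_max_a - T_a)` for `a` in
#' `{p, d}`.  For any bounded non-negative H the traces remain inside
#' `[0, T_max_a]`.
#'
#' @param elig an [eligibility_state()].
#' @param H Hebbian coincidence matrix (same shape as the traces), >= 0.
#' @param dt timestep (ms).
#' @return The updated `eligibility_state`.
#' @export
update_eligibility <- function(elig, H, dt = 1) {
  if (any(H < 0)) stop("Hebbian term must be non-negative", call. = FALSE)
  Tp <- elig$T_p
  Td <- elig$T_d
  Tp <- Tp + (dt / elig$tau_p) * (-Tp + elig$eta_p * H * (elig$T_max_p - Tp))
  Td <- Td + (dt / elig$tau_d) * (-Td + elig$eta_d * H * (elig$T_max_d - Td))
  elig$T_p <- pmin(pmax(Tp, 0), elig$T_max_p)
  elig$T_d <- pmin(pmax(Td, 0), elig$T_max_d)
  elig
}

#' Analytic steady state of an eligibility trace
#'
#' Under constant Hebbian drive H the trace ODE has the fixed point
#' `T* = eta * H * T_max / (1 + eta * H)`; used as an oracle in tests and
#' handy for reasoning about trace saturation.
#'
#' @param H constant Hebbian drive.
#' @param eta activation rate constant.
#' @param T_max saturation level.
#' @return The fixed-point trace level.
#' @export
eligibility_steady_state <- function(H, eta, T_max) {
  eta * H * T_max / (1 + eta * H)
}

#' Competitive two-trace weight update
#'
#' `dW = eta * D * (T_p - T_d) * dt`: reinforcement converts the *difference*
#' of the LTP and LTD traces into a weight change, so the same positive D can
#' potentiate (where T_p > T_d) or depress (where T_p < T_d).  Excitatory
#' weights are floored at zero and optionally capped.
#'
#' @param W weight matrix.
#' @param D signed reinforcement (Hz, scalar).
#' @param T_p,T_d trace matrices aligned with `W`.
#' @param eta learning rate (scalar or matrix).
#' @param dt timestep (ms).
#' @param w_max optional upper cap.
#' @return The updated weight matrix.
#' @export
dttl_weight_update <- function(W, D, T_p, T_d, eta, dt = 1, w_max = Inf) {
  if (D == 0) return(W)
  pmin(pmax(W + eta * D * (T_p - T_d) * dt, 0), w_max)
}

#' Dopamine-modulated Hebbian update
#'
#' `dW = eta * D * r_post * r_pre * dt`, used for the Messenger-to-GABA
#' pathway: coincident Messenger and GABA firing under positive D recruits
#' inhibition of the DA population, which is the mechanism that suppresses
#' the reward-evoked dopamine response; negative D depresses the same
#' weights.  Weights are floored at zero.
#'
#' @param W weight matrix (`n_post` x `n_pre`).
#' @param D signed reinforcement (Hz, scalar).
#' @param r_pre,r_post rate estimates (spikes/ms).
#' @param eta learning rate (scalar or matrix).
#' @param dt timestep (ms).
#' @param w_max optional upper cap.
#' @return The updated weight matrix.
#' @export
da_hebbian_update <- function(W, D, r_pre, r_post, eta, dt = 1, w_max = Inf) {
  if (D == 0) return(W)
  if (any(r_pre < 0) || any(r_post < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  pmin(pmax(W + eta * D * outer(r_post, r_pre) * dt, 0), w_max)
}

#' Value-variant weight update
#'
#' Identical in form to [dttl_weight_update()] but driven by the
#' non-suppressed neuromodulator A(t) instead of D(t).  A(t) has the same
#' thresholded functional form as D(t) but is computed from a shadow DA
#' population that ignores learned inhibition, so it keeps reporting the
#' reward magnitude after the dopamine response proper has been suppressed —
#' this makes the learned cue response scale with reward value.
#'
#' @param W weight matrix.
#' @param A signed neuromodulator value (Hz, scalar).
#' @param T_p,T_d trace matrices.
#' @param eta learning rate.
#' @param dt timestep (ms).
#' @param w_max optional upper cap.
#' @param enabled set by the caller from the config flag; calling with the
#'   variant disabled is a configuration error.
#' @return The updated weight matrix.
#' @export
value_variant_update <- function(W, A, T_p, T_d, eta, dt = 1, w_max = Inf,
                                 enabled = TRUE) {
  if (!enabled) {
    stop("value-tracking variant is disabled in this configuration",
         call. = FALSE)
  }
  dttl_weight_update(W, A, T_p, T_d, eta, dt, w_max)
}

#' Fixed-point residual of the two-trace rule over a trial
#'
#' The learning rule has its fixed point where the trial integral
#' `int D(t) (T_p(t) - T_d(t)) dt` vanishes.  The residual is returned
#' together with its decomposition into a cue-window and a reward-window
#' part, which is how the approach to the fixed point is usually diagnosed:
#' early in training only the reward window contributes; at convergence the
#' two windows cancel (or D has been suppressed entirely).
#'
#' @param D_trace reinforcement time series over one trial.
#' @param Tp_trace,Td_trace trace time series on the same grid (for one
#'   synapse, or already averaged).
#' @param dt grid spacing (ms).
#' @param cs_window,us_window optional `c(start, end)` (ms) windows for the
#'   decomposition.
#' @return List with `residual`, `cs_part`, `us_part`.
#' @export
fixed_point_residual <- function(D_trace, Tp_trace, Td_trace, dt = 1,
                                 cs_window = NULL, us_window = NULL) {
  stopifnot(length(D_trace) == length(Tp_trace),
            length(D_trace) == length(Td_trace))
  integrand <- D_trace * (Tp_trace - Td_trace)
  part <- function(win) {
    if (is.null(win)) return(NA_real_)
    t <- (seq_along(integrand) - 1) * dt
    sum(integrand[t >= win[1] & t < win[2]]) * dt
  }
  list(residual = sum(integrand) * dt,
       cs_part = part(cs_window),
       us_part = part(us_window))
}
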