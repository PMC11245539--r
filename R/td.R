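#' Configuration for the TD(lambda) reference model
#'
#' Tabular temporal-difference learning on a complete-serial-compound (CSC)
#' temporal basis: the cue triggers a chain of microstates, one per time bin,
#' and the value function is a weighted sum over them.  Cue and reward
#' signals are smoothed with a Gaussian in time.  Before cue onset no
#' microstate is active (the feature vector is identically zero), so the
#' value before the cue and beyond the trial end is exactly zero.
#'
#' @param trial_length trial duration (ms).
#' @param dt_bin bin width (ms).
#' @param cue_time,reward_time event centres (ms).
#' @param lambda eligibility-trace decay in `[0, 1]`.
#' @param gamma discount factor in `(0, 1]`.
#' @param alpha_lr learning rate.
#' @param gaussian_width temporal std of the cue/reward Gaussians (ms);
#'   `0` gives the sharp tabular CSC.
#' @param reward_magnitude total delivered reward per trial.
#' @param n_trials number of training trials.
#' @return A list of class `td_config`.
#' @export
td_config <- function(trial_length = 1300, dt_bin = 10, cue_time = 100,
                      reward_time = 1100, lambda = 0.975, gamma = 1,
                      alpha_lr = 0.05, gaussian_width = 50,
                      reward_magnitude = 1, n_trials = 100) {
  stopifnot(lambda >= 0, lambda <= 1, gamma > 0, gamma <= 1,
            reward_time < trial_length, cue_time < reward_time)
  n_bins <- floor(trial_length / dt_bin)
  structure(list(trial_length = trial_length, dt_bin = dt_bin,
                 n_bins = n_bins, n_states = n_bins,
                 cue_bin = floor(cue_time / dt_bin) + 1L,
                 reward_bin = floor(reward_time / dt_bin) + 1L,
                 lambda = lambda, gamma = gamma, alpha_lr = alpha_lr,
                 gaussian_width = gaussian_width,
                 reward_magnitude = reward_magnitude,
                 n_trials = n_trials),
            class = "td_config")
}

# features: column t of the (n_states x n_bins) matrix is the microstate
# activation at bin t; zero before cue onset, a (possibly Gaussian-smeared)
# bump over the chain after it
td_features <- function(cfg) {
  X <- matrix(0, cfg$n_states, cfg$n_bins)
  w <- cfg$gaussian_width / cfg$dt_bin
  for (t in seq_len(cfg$n_bins)) {
    if (t < cfg$cue_bin) next
    centre <- t - cfg$cue_bin + 1L
    if (w <= 0) {
      X[centre, t] <- 1
    } else {
      prof <- stats::dnorm(seq_len(cfg$n_states), centre, w)
      X[, t] <- prof / sum(prof)
    }
  }
  X
}

td_reward_signal <- function(cfg) {
  w <- cfg$gaussian_width / cfg$dt_bin
  if (w <= 0) {
    r <- numeric(cfg$n_bins)
    r[cfg$reward_bin] <- cfg$reward_magnitude
    return(r)
  }
  prof <- stats::dnorm(seq_len(cfg$n_bins), cfg$reward_bin, w)
  cfg$reward_magnitude * prof / sum(prof)
}

#' One trial of TD(lambda)
#'
#' Runs the update `V(s) <- V(s) + alpha * (r(s') + gamma V(s') - V(s))`
#' over the CSC chain with accumulating eligibility traces.  The
#' reward-prediction errors of the whole trial are computed against the
#' value function as it stood at trial start, and the weight update is
#' applied once at the trial end (per-trial batch updating; with `lambda =
#' 0` this is exactly the tabular TD(0) update).  Eligibility resets at
#' trial start.
#'
#' @param V value weights over microstates (length `n_states`).
#' @param cfg a [td_config()].
#' @return List with updated `V`, the per-bin RPE vector `delta`, and the
#'   final eligibility vector `e`.
#' @export
td_lambda_trial <- function(V, cfg) {
  X <- td_features(cfg)
  r <- td_reward_signal(cfg)
  B <- cfg$n_bins
  v <- as.numeric(crossprod(X, V))       # value at each bin
  v_next <- c(v[-1], 0)                  # terminal value is zero
  delta <- r + cfg$gamma * v_next - v
  e <- numeric(cfg$n_states)
  dW <- numeric(cfg$n_states)
  gl <- cfg$gamma * cfg$lambda
  for (t in seq_len(B)) {
    e <- gl * e + X[, t]
    dW <- dW + delta[t] * e
  }
  list(V = V + cfg$alpha_lr * dW, delta = delta, e = e)
}

#' Run a full TD training session
#'
#' @param cfg a [td_config()].
#' @return List of class `td_session`: `delta` (bins x trials RPE matrix),
#'   `V` (final value weights), `integrated` (per-trial summed RPE) and the
#'   config.
#' @export
run_td <- function(cfg) {
  V <- numeric(cfg$n_states)
  delta <- matrix(0, cfg$n_bins, cfg$n_trials)
  for (i in seq_len(cfg$n_trials)) {
    out <- td_lambda_trial(V, cfg)
    V <- out$V
    delta[, i] <- out$delta
  }
  structure(list(delta = delta, V = V, integrated = colSums(delta),
                 config = cfg),
            class = "td_session")
}

#' Per-trial integrated reward-prediction error
#'
#' Sum of the RPE over all bins of each trial.  For an undiscounted model
#' this quantity is conserved across training (it equals the delivered
#' reward mass every trial); with discounting it decreases monotonically.
#'
#' @param delta RPE matrix (bins x trials) or a `td_session`.
#' @return Numeric vector, one value per trial.
#' @export
integrated_rpe <- function(delta) {
  if (inherits(delta, "td_session")) delta <- delta$delta
  colSums(as.matrix(delta))
}

#' Position of the RPE bump
#'
#' Index of the bin with the largest RPE; ties break toward the earliest
#' bin.  Tracking this across training distinguishes TD(0) (a bump that
#' travels backward from the reward bin to the cue bin) from TD(lambda) with
#' a long trace (no travelling bump).
#'
#' @param delta RPE vector for one trial.
#' @return Integer bin index.
#' @export
bump_position <- function(delta) {
  if (all(delta == 0)) {
    stop("bump position undefined: all-zero RPE trace", call. = FALSE)
  }
  which.max(delta)
}
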