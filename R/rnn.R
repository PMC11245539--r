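#' Configuration for the fixed random RNN
#'
#' A recurrent rate network with random Gaussian weights
#' `W ~ N(0, g/sqrt(K))` (K = number of units, full connectivity) and a
#' sigmoidal transfer function, used to probe whether an *untrained*
#' recurrent network can serve as a repeatable temporal basis.  Each
#' stimulus label gets a unique, normally distributed input projection that
#' is pulsed as a 100 ms step function.
#'
#' @param n_units number of units.
#' @param gain weight gain g.
#' @param tau_net unit time constant (ms).
#' @param input_duration stimulus pulse width (ms).
#' @param input_strength scaling of the input projections.
#' @param phi `"logistic"` or `"tanh"` transfer function.
#' @param dt integration timestep (ms).
#' @param seed seed for weights and input projections.
#' @return A list of class `rnn_config`.
#' @export
rnn_config <- function(n_units = 500, gain = 1.5, tau_net = 50,
                       input_duration = 100, input_strength = 1,
                       phi = c("logistic", "tanh"), dt = 1, seed = 1) {
  phi <- match.arg(phi)
  stopifnot(n_units > 0, tau_net > 0, gain >= 0)
  structure(list(n_units = as.integer(n_units), gain = gain,
                 tau_net = tau_net, input_duration = input_duration,
                 input_strength = input_strength, phi = phi, dt = dt,
                 seed = seed),
            class = "rnn_config")
}

rnn_build <- function(cfg, labels) {
  set.seed(child_seed(cfg$seed, "rnn-weights"))
  W <- matrix(stats::rnorm(cfg$n_units^2, 0, cfg$gain / sqrt(cfg$n_units)),
              cfg$n_units, cfg$n_units)
  inputs <- list()
  for (lab in sort(unique(labels))) {
    set.seed(child_seed(cfg$seed, paste0("rnn-input:", lab)))
    inputs[[lab]] <- stats::rnorm(cfg$n_units) * cfg$input_strength
  }
  list(W = W, inputs = inputs)
}

#' Simulate the fixed RNN for a stimulus sequence
#'
#' Forward-Euler integration of
#' `tau_net du/dt = -u + W phi(u) + input(t)`, deterministic given the
#' config seed (weights and projections are drawn from derived streams, so
#' the same seed and sequence always give the same trajectory).
#'
#' @param cfg an [rnn_config()].
#' @param sequence data frame with columns `label` and `onset` (ms).
#' @param duration total simulated time (ms).
#' @return Matrix (time x units) of unit activities, with the time grid in
#'   attribute `"time_ms"`.
#' @export
simulate_rnn <- function(cfg, sequence, duration) {
  stopifnot(all(c("label", "onset") %in% names(sequence)),
            all(sequence$onset >= 0), all(sequence$onset < duration))
  net <- rnn_build(cfg, sequence$label)
  phi <- if (cfg$phi == "logistic") function(x) 1 / (1 + exp(-x)) else tanh
  steps <- round(duration / cfg$dt)
  u <- numeric(cfg$n_units)
  out <- matrix(0, steps, cfg$n_units)
  tgrid <- (seq_len(steps) - 1) * cfg$dt
  for (t in seq_len(steps)) {
    inp <- numeric(cfg$n_units)
    now <- tgrid[t]
    for (i in seq_len(nrow(sequence))) {
      if (now >= sequence$onset[i] &&
          now < sequence$onset[i] + cfg$input_duration) {
        inp <- inp + net$inputs[[sequence$label[i]]]
      }
    }
    du <- (-u + as.numeric(net$W %*% phi(u)) + inp) * (cfg$dt / cfg$tau_net)
    u <- u + du
    out[t, ] <- u
  }
  attr(out, "time_ms") <- tgrid
  out
}

#' Project trajectories onto principal components
#'
#' PCA of the concatenated trajectories (centred, unscaled), returning each
#' trajectory's path in the top-k component space.  Variance explained is
#' non-increasing across components by construction.
#'
#' @param trajectories a single (time x units) matrix or a list of them.
#' @param k number of components.
#' @return List with `scores` (list of time x k matrices), `sdev` and
#'   `rotation` from the underlying eigendecomposition.
#' @export
project_principal_components <- function(trajectories, k = 2) {
  if (is.matrix(trajectories)) trajectories <- list(trajectories)
  if (any(vapply(trajectories, nrow, 0L) < 2)) {
    stop("need at least 2 time samples per trajectory", call. = FALSE)
  }
  X <- do.call(rbind, trajectories)
  if (all(apply(X, 2, stats::var) < .Machine$double.eps)) {
    stop("degenerate (constant) trajectory: PCA undefined", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  idx <- cumsum(vapply(trajectories, nrow, 0L))
  start <- c(1, utils::head(idx, -1) + 1)
  scores <- Map(function(a, b) pc$x[a:b, seq_len(k), drop = FALSE],
                start, idx)
  list(scores = scores, sdev = pc$sdev, rotation = pc$rotation)
}

#' Divergence of two trajectories after an alignment time
#'
#' Mean Euclidean distance between the state vectors of two equally sampled
#' trajectories, from `align_time` onward.  Identical trajectories give 0;
#' the measure is symmetric in its arguments.
#'
#' @param traj_a,traj_b (time x units) matrices on the same grid.
#' @param align_time start of the comparison window (ms).
#' @param dt grid spacing (ms); taken from the trajectory attribute when
#'   available.
#' @return Mean distance (scalar).
#' @export
trajectory_divergence <- function(traj_a, traj_b, align_time = 0,
                                  dt = NULL) {
  stopifnot(all(dim(traj_a) == dim(traj_b)))
  tg <- attr(traj_a, "time_ms")
  if (is.null(tg)) {
    if (is.null(dt)) dt <- 1
    tg <- (seq_len(nrow(traj_a)) - 1) * dt
  }
  sel <- tg >= align_time
  d <- sqrt(rowSums((traj_a[sel, , drop = FALSE] -
                       traj_b[sel, , drop = FALSE])^2))
  mean(d)
}
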