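#' Sliding-criterion auROC between two spike-count samples
#'
#' The discriminability measure used for all population summaries: within a
#' bin, the distribution of spike counts under a condition is compared to
#' the baseline distribution by sliding an integer criterion from zero to
#' the maximum observed count and tracing P(active > criterion) against
#' P(baseline > criterion); the endpoints (0,0) and (1,1) are appended and
#' the area under the curve is computed by the trapezoid rule.  0.5 means
#' the distributions are indiscriminable, 1 a maximally discriminable
#' increase, 0 a maximally discriminable decrease.
#'
#' @param counts_baseline,counts_active integer spike counts per trial.
#' @return auROC value in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0, 1, 0, 1), c(0, 1, 0, 1))   # 0.5
#' auroc(rep(0, 25), rep(5, 25))         # 1
auroc <- function(counts_baseline, counts_active) {
  if (!length(counts_baseline) || !length(counts_active)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  cmax <- max(counts_baseline, counts_active)
  crit <- seq(-1L, cmax)            # criterion -1 contributes the (1,1) end
  fpr <- vapply(crit, function(c) mean(counts_baseline > c), 0)
  tpr <- vapply(crit, function(c) mean(counts_active > c), 0)
  x <- c(fpr, 0)
  y <- c(tpr, 0)
  # criteria ascending means x descending; integrate along decreasing x
  sum((x[-length(x)] - x[-1]) * (y[-length(y)] + y[-1]) / 2)
}

#' Per-neuron, per-bin auROC of a session against baseline
#'
#' Tiles the trial into fixed bins (50 ms), counts spikes per neuron, bin
#' and trial in both sessions, and computes the sliding-criterion auROC of
#' the active condition against baseline for every neuron and bin.
#'
#' @param session a `flex_session` recorded with spikes (the condition of
#'   interest).
#' @param baseline_session a no-stimulus `flex_session` with spikes.
#' @param bin_ms bin width (ms).
#' @param n_trials trials per condition used in the comparison (the last
#'   `n_trials` of each session).
#' @param population which population's neurons to analyse.
#' @return List of class `auroc_result`: `auroc` (neurons x bins matrix),
#'   `bin_edges` (ms), `n_trials_baseline`, `n_trials_active`.
#' @export
binned_auroc <- function(session, baseline_session, bin_ms = 50,
                         n_trials = 25, population = "DA") {
  for (nm in c("session", "baseline_session")) {
    s <- get(nm)
    if (is.null(s$spikes)) {
      stop(nm, " was recorded without spike tables", call. = FALSE)
    }
    avail <- dim(s$rates)[3]
    if (avail < n_trials) {
      stop(nm, " has only ", avail, " trials, need ", n_trials,
           call. = FALSE)
    }
  }
  trial_len <- session$protocol$trial_length
  n_bins <- floor(trial_len / bin_ms)
  n_neur <- session$network$pops[[population]]$params$n

  count_array <- function(s) {
    nt <- dim(s$rates)[3]
    use <- (nt - n_trials + 1):nt
    sp <- s$spikes[s$spikes$population == population &
                     s$spikes$trial %in% use, ]
    arr <- array(0L, c(n_neur, n_bins, n_trials))
    if (nrow(sp)) {
      b <- pmin(floor((sp$time_ms - 1e-9) / bin_ms) + 1L, n_bins)
      tr <- match(sp$trial, use)
      idx <- cbind(sp$neuron_id, b, tr)
      for (i in seq_len(nrow(idx))) {
        arr[idx[i, 1], idx[i, 2], idx[i, 3]] <-
          arr[idx[i, 1], idx[i, 2], idx[i, 3]] + 1L
      }
    }
    arr
  }
  act <- count_array(session)
  base <- count_array(baseline_session)
  res <- matrix(NA_real_, n_neur, n_bins)
  for (i in seq_len(n_neur)) {
    for (b in seq_len(n_bins)) {
      res[i, b] <- auroc(base[i, b, ], act[i, b, ])
    }
  }
  structure(list(auroc = res, bin_edges = seq(0, n_bins) * bin_ms,
                 n_trials_baseline = n_trials, n_trials_active = n_trials,
                 population = population),
            class = "auroc_result")
}

#' Integrated dopamine release per trial
#'
#' Time-integral of the signed reinforcement D(t) over each trial
#' (Hz * ms).  On a naive reward-only trial this defines the baseline bar
#' against which the transient excess of integrated release during training
#' is measured.
#'
#' @param session a `flex_session`, or a D matrix (steps x trials).
#' @param dt grid spacing (ms) when a bare matrix is given.
#' @return Numeric vector, one integral per trial.
#' @export
integrated_da <- function(session, dt = NULL) {
  if (inherits(session, "flex_session")) {
    return(colSums(as.matrix(session$D)) * session$dt)
  }
  if (is.null(dt)) dt <- 1
  colSums(as.matrix(session)) * dt
}

#' Duration of the Timer firing envelope
#'
#' Time from cue onset until the (smoothed) mean Timer rate last falls
#' below a fraction of its peak.  As training progresses this duration
#' grows until it spans the cue-reward delay.
#'
#' @param timer_rates mean Timer rate time series (Hz) for one trial.
#' @param dt grid spacing (ms).
#' @param cs_onset cue onset (ms).
#' @param threshold_fraction envelope threshold as a fraction of the peak
#'   (the low default reflects that the cue-onset transient, not the
#'   sustained plateau, sets the peak).
#' @param smooth_ms moving-average smoothing window (ms).
#' @return Duration (ms).
#' @export
timer_duration <- function(timer_rates, dt = 1, cs_onset = 100,
                           threshold_fraction = 0.1, smooth_ms = 40) {
  r <- smooth_series(timer_rates, max(1, round(smooth_ms / dt)))
  tgrid <- (seq_along(r) - 1) * dt
  post <- tgrid >= cs_onset
  peak <- max(r[post])
  if (!is.finite(peak) || peak <= 1) {
    stop("no suprathreshold Timer activity after cue onset", call. = FALSE)
  }
  above <- post & (r >= threshold_fraction * peak)
  if (!any(above)) {
    stop("no suprathreshold Timer activity after cue onset", call. = FALSE)
  }
  max(tgrid[above]) - cs_onset
}

#' Time of the Messenger firing peak
#'
#' Argmax of the smoothed mean Messenger rate; after learning this peak
#' sits at the cue-predicted reward time.
#'
#' @param messenger_rates mean Messenger rate time series (Hz).
#' @param dt grid spacing (ms).
#' @param smooth_ms moving-average smoothing window (ms).
#' @return Peak time (ms).
#' @export
messenger_peak_time <- function(messenger_rates, dt = 1, smooth_ms = 50) {
  r <- smooth_series(messenger_rates, max(1, round(smooth_ms / dt)))
  if (max(r) - min(r) < .Machine$double.eps^0.5) {
    stop("flat Messenger rate trace: peak undefined", call. = FALSE)
  }
  (which.max(r) - 1) * dt
}

# centred moving average with edge shrinkage
smooth_series <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  half <- floor(window / 2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    a <- max(1, i - half)
    b <- min(n, i + half)
    out[i] <- mean(x[a:b])
  }
  out
}

#' Running average over trials
#'
#' @param series numeric vector (e.g. a per-trial metric).
#' @param window window width in samples.
#' @param mode `"trailing"` (mean of the current and previous
#'   `window - 1` values) or `"centered"`.
#' @return Smoothed series of the same length; a constant series is a fixed
#'   point, and `window = 1` is the identity.
#' @export
running_average <- function(series, window = 10,
                            mode = c("trailing", "centered")) {
  mode <- match.arg(mode)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  n <- length(series)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (mode == "trailing") {
      a <- max(1, i - window + 1)
      out[i] <- mean(series[a:i])
    } else {
      half <- floor(window / 2)
      out[i] <- mean(series[max(1, i - half):min(n, i + half)])
    }
  }
  out
}

#' Synthetic spike-count table generator
#'
#' Draws independent Poisson spike counts at specified per-bin rates — the
#' fixture generator used to exercise the analysis metrics without running
#' the simulator.
#'
#' @param rate_hz firing rate (Hz); scalar or one value per bin.
#' @param n_trials number of trials.
#' @param n_bins number of bins.
#' @param bin_ms bin width (ms).
#' @return Integer matrix (trials x bins) of spike counts.
#' @export
synth_spike_counts <- function(rate_hz, n_trials = 25, n_bins = 1,
                               bin_ms = 50) {
  lam <- rep_len(rate_hz, n_bins) * bin_ms / 1000
  matrix(stats::rpois(n_trials * n_bins, rep(lam, each = n_trials)),
         n_trials, n_bins)
}

#' Synthetic rate-profile session fixture
#'
#' Builds an artificial mean-rate time series from a baseline plus
#' rectangular and Gaussian components; used to validate the envelope and
#' peak estimators against known ground truth.
#'
#' @param trial_length length (ms).
#' @param dt grid spacing (ms).
#' @param baseline constant floor (Hz).
#' @param rect optional `c(onset, offset, height)` rectangle.
#' @param bump optional `c(centre, sd, height)` Gaussian bump.
#' @return Numeric rate vector.
#' @export
synth_rate_profile <- function(trial_length = 1300, dt = 1, baseline = 0,
                               rect = NULL, bump = NULL) {
  tgrid <- seq(0, trial_length - dt, by = dt)
  r <- rep(baseline, length(tgrid))
  if (!is.null(rect)) {
    r <- r + ifelse(tgrid >= rect[1] & tgrid < rect[2], rect[3], 0)
  }
  if (!is.null(bump)) {
    r <- r + bump[3] * exp(-(tgrid - bump[1])^2 / (2 * bump[2]^2))
  }
  r
}
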