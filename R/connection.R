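#' Construct a weighted projection between two populations
#'
#' A connection group bundles the weight matrix (postsynaptic neurons in
#' rows), the sign class of the projection, the synaptic-activation class the
#' presynaptic population transmits through, the transmission delay, and —
#' for plastic groups — the learning rule with its eligibility-trace state.
#'
#' @param pre,post names of the presynaptic and postsynaptic populations.
#' @param W weight matrix (`n_post` x `n_pre`), or a scalar expanded to a
#'   dense matrix.  Excitatory groups must be non-negative, inhibitory groups
#'   non-positive.
#' @param sign `+1` (excitatory) or `-1` (inhibitory).
#' @param s_class synaptic activation class used by this projection
#'   (`"E"`, `"I"`, `"VTAe"` or `"VTAi"`).
#' @param delay_ms transmission delay (ms).
#' @param n_pre,n_post population sizes (used when `W` is scalar).
#' @param plasticity `NULL` for a fixed group, otherwise a list created by
#'   the network builder describing the rule (`"dttl"` or `"da_hebb"`), the
#'   trace parameter set, the learning-rate matrix and the weight cap.
#' @return A list of class `connection_group`.
#' @export
connection_group <- function(pre, post, W, sign = 1, s_class = "E",
                             delay_ms = 10, n_pre = NULL, n_post = NULL,
                             plasticity = NULL) {
  if (length(W) == 1 && !is.matrix(W)) {
    stopifnot(!is.null(n_pre), !is.null(n_post))
    W <- matrix(W, n_post, n_pre)
  }
  if (sign > 0 && any(W < 0)) {
    stop("excitatory connection group has negative weights", call. = FALSE)
  }
  if (sign < 0 && any(W > 0)) {
    stop("inhibitory connection group has positive weights", call. = FALSE)
  }
  structure(list(pre = pre, post = post, W = W, sign = sign,
                 s_class = s_class, delay_ms = delay_ms,
                 plasticity = plasticity),
            class = "connection_group")
}

#' Conductance delivered by a projection
#'
#' Computes `g_i = sum_j |W_ij| s_j` from the (already delay-shifted)
#' presynaptic activations.  The sign of the group decides whether the result
#' enters the membrane equation as an excitatory or inhibitory conductance;
#' the returned conductance itself is always non-negative.
#'
#' @param group a [connection_group()].
#' @param s_pre presynaptic activation vector, delayed by the group's
#'   transmission delay.
#' @return Numeric vector of conductances (nS), one per postsynaptic neuron.
#' @export
conductance <- function(group, s_pre) {
  if (ncol(group$W) != length(s_pre)) {
    stop("activation vector length ", length(s_pre),
         " does not match presynaptic size ", ncol(group$W), call. = FALSE)
  }
  as.numeric(abs(group$W) %*% s_pre)
}
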