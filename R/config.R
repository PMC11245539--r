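#' Default model configuration
#'
#' Returns the full nested configuration of the simulator with published
#' defaults for every parameter of the spiking model: leaky integrate-and-fire
#' membrane constants, saturating synaptic activations, the dopamine signal
#' thresholds, eligibility-trace constants for recurrent and feed-forward
#' pathways, fixed connection strengths, stimulus statistics and integration
#' settings.  All quantities are in mV, ms, nS, pF and pA (these units are
#' mutually consistent: nS*mV = pA and pA*ms/pF = mV, so no conversion layer
#' is needed anywhere in the integrator).
#'
#' Values that the published parameter table does not pin down (tonic VTA
#' drive in pA, stimulus projection strengths, initial plastic weights,
#' per-pathway learning gains) are calibration constants of this
#' implementation; see the methods vignette for how each was chosen.
#'
#' @param ... named overrides merged over the defaults, e.g.
#'   `flex_config(sim = list(dt = 0.5))`.  Unknown keys are rejected.
#' @return A nested list of class `flex_config`.
#' @export
#' @examples
#' cfg <- flex_config()
#' cfg$neuron$rho            # 1/7
#' cfg$plasticity$d0         # 5 Hz dopamine baseline
flex_config <- function(...) {
  cfg <- list(
    sim = list(
      dt = 1,                  # integration timestep (ms), forward Euler
      delay_ms = 10,           # inter-population transmission delay
      intra_delay_ms = 1       # recurrent (within-population) delay
    ),
    neuron = list(
      n_per_pop = 100,
      C_m   = 200,             # pF
      g_L   = 10,              # nS
      E_L   = -60,             # mV
      E_E   = -5,
      E_I   = -70,
      v_th_E = -55,
      v_th_I = -50,
      v_rest = -60,
      v_hold = -61,
      t_ref  = 3,              # ms, effective refractory period
      rho    = 1 / 7,          # fractional synaptic activation increment
      tau_r  = 40,             # ms, rate-estimation (firing-rate window)
      tau_s  = list(E = 80, I = 20, VTAe = 20, VTAi = 10)  # ms per class
    ),
    noise = list(
      pfc_sd  = 20,            # pA white-noise std, Timer/Messenger neurons
      vta_sd  = 120,           # pA white-noise std, VTA neurons
      tonic_i    = -170,       # pA resting bias, column interneurons: makes
                               # them release the Messengers as soon as the
                               # Timer envelope ends
      tonic_da   = 30.3,       # pA constant drive, DA neurons (calibrated)
      tonic_gaba = 68.4        # pA constant drive, GABA neurons (calibrated)
    ),
    network = list(
      columns = "CS1",         # one feature column per conditioned stimulus
      projection_sparsity = 0.1,   # CS->DA and US->DA connection probability
      fixed_weights = list(
        t_m    = 0.5,          # Timer -> Messenger (EE), nS per synapse
        i_m    = -20,          # column Inhibitory -> Messenger (EI)
        t_i    = 0.3,          # Timer -> Inhibitory (IE)
        m_i    = 1,            # Messenger -> Inhibitory (IE)
        gaba_da = -1.5,        # VTA GABA -> DA (EI)
        cs_t   = 0.18,         # stimulus units -> Timer (fixed drive)
        cs_i   = 0.8,          # stimulus units -> column Inhibitory
                               # (feed-forward inhibition at cue onset)
        us_da  = 0.8           # stimulus units -> DA (gustatory projection)
      ),
      init_weights = list(
        timer_rec = 0.025,     # Timer -> Timer, naive persistence well short
                               # of the cue-reward delay
        cs_da = 0,             # no CS-evoked dopamine before learning
        m_gaba = 0             # no learned inhibition before learning
      )
    ),
    stimulus = list(
      rate = 30,               # Hz, Poisson pulse rate p_r
      duration = 100,          # ms, default CS/US pulse width
      n_units = 100            # input units per stimulus channel
    ),
    plasticity = list(
      d0 = 5,                  # Hz, dopamine baseline rate r0
      theta = 2,               # Hz, neutral half-width
      alpha_pfc = 1,           # 1/Hz, Hebbian suppression for positive D
      pfc_floor = 0.1,         # lower clamp of the (1 + alpha*D) divisor
      recurrent = list(
        tau_p = 1800, tau_d = 800,
        T_max_p = 0.003, T_max_d = 0.0033,
        eta_p = 300, eta_d = 135
      ),
      feedforward = list(
        tau_p = 2000, tau_d = 800,
        T_max_p = 0.0015, T_max_d = 0.004,
        eta_p = 650, eta_d = 40
      ),
      hebb_rate_scale = 60,    # Hz; rate normalisation of the Hebbian
                               # products, placing eta*H near trace
                               # saturation during sustained activity
      eta_rec = 0.00015,       # 1/ms, recurrent learning rate
      eta_ff_sd = 1.5,         # per-synapse |N(0, sd)| feed-forward rates
      eta_vta_sd = 0.01,       # per-synapse |N(0, sd)| Messenger->GABA rates
      gain_rec = 30,           # dimensionless pathway gains (see vignette)
      gain_ff = 0.4,
      gain_vta = 0.5,
      w_max = list(timer_rec = 0.07, cs_da = 1.2, m_gaba = 1),
      use_A_variant = FALSE,   # value-tracking neuromodulator A(t)
      m_gaba_dttl = FALSE,     # use two-trace rule for M->GABA
      tau_e = 10, tau_ea = 20  # published but unreferenced; kept inert
    )
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_config(cfg, overrides, path = "")
  validate_config(cfg)
  structure(cfg, class = "flex_config")
}

# recursive merge; every override key must already exist in the defaults
merge_config <- function(base, over, path = "") {
  if (is.null(names(over)) || any(names(over) == "")) {
    stop("configuration overrides must be named (at '", path, "')",
         call. = FALSE)
  }
  for (key in names(over)) {
    here <- paste0(path, "$", key)
    if (!key %in% names(base)) {
      stop("unknown configuration key: '", sub("^\\$", "", here), "'",
           call. = FALSE)
    }
    if (is.list(base[[key]]) && is.list(over[[key]])) {
      base[[key]] <- merge_config(base[[key]], over[[key]], here)
    } else {
      base[[key]] <- over[[key]]
    }
  }
  base
}

#' Load a configuration from a YAML file
#'
#' YAML is the canonical configuration dialect of the package.  The file may
#' specify any subset of keys; they are merged over [flex_config()] defaults
#' and the result is validated.  Unknown keys and invariant violations are
#' rejected with the offending key path.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `flex_config` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(flex_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  over <- yaml::read_yaml(path)
  if (is.null(over)) return(flex_config())
  do.call(flex_config, over)
}

validate_config <- function(cfg) {
  nb <- cfg$neuron
  chk <- function(ok, msg) if (!ok) stop("invalid configuration: ", msg,
                                         call. = FALSE)
  chk(cfg$sim$dt > 0, "sim$dt must be > 0")
  chk(nb$C_m > 0 && nb$g_L > 0, "capacitance and conductances must be > 0")
  chk(nb$rho > 0 && nb$rho <= 1, "neuron$rho must lie in (0, 1]")
  chk(nb$v_hold <= nb$v_rest, "v_hold must be <= v_rest")
  chk(nb$v_rest < nb$v_th_E && nb$v_th_E < nb$E_E,
      "need v_rest < v_th_E < E_E")
  chk(nb$E_I <= nb$E_L, "E_I must be <= E_L")
  chk(all(unlist(nb$tau_s) > 0), "synaptic time constants must be > 0")
  chk(nb$tau_r > 0, "neuron$tau_r must be > 0")
  chk(nb$t_ref >= 0, "t_ref must be >= 0")
  chk(cfg$plasticity$theta >= 0, "plasticity$theta must be >= 0")
  chk(cfg$plasticity$d0 > 0, "plasticity$d0 must be > 0")
  chk(cfg$network$projection_sparsity >= 0 &&
        cfg$network$projection_sparsity <= 1,
      "network$projection_sparsity must lie in [0, 1]")
  chk(cfg$stimulus$rate >= 0, "stimulus$rate must be >= 0")
  fw <- cfg$network$fixed_weights
  chk(all(unlist(fw[c("t_m", "t_i", "m_i", "cs_t", "cs_i", "us_da")]) >= 0),
      "excitatory fixed weights must be >= 0")
  chk(all(unlist(fw[c("i_m", "gaba_da")]) <= 0),
      "inhibitory fixed weights must be <= 0")
  invisible(TRUE)
}

#' Digest of a resolved configuration
#'
#' MD5 of the serialized configuration; recorded in run manifests so that a
#' recording can be matched to the exact parameter set that produced it.
#'
#' @param cfg a `flex_config` object.
#' @return A 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(cfg), tf, version = 3, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Derive a child seed from a master seed and a stream label
#'
#' One master seed drives every stochastic component; each module draws from
#' its own deterministic child stream so that toggling one component (say, the
#' stimulus realisation) does not perturb the noise of another.
#'
#' @param seed master seed (integer).
#' @param stream character label of the consuming stream.
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @export
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (as.double(seed) * 69069 + h * 3643 + 12345) %% 2147483647
  as.integer(val)
}
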