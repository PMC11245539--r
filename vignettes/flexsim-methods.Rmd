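---
title: "Model and methods: a plastic temporal basis for dopaminergic reward prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flexsim)
```

# The problem

Temporal-difference (TD) accounts of dopaminergic reward-prediction-error
(RPE) signalling assume a *fixed* temporal basis: every cue must, before any
learning, trigger its own reliable chain of "microstates" spanning every
delay that might ever separate it from a reward.  `flexsim` implements the
alternative hypothesis: the temporal basis itself is *learned*, co-evolving
with the dopamine signal during trace conditioning, and only for cues that
predict reward.  The package contains

* a conductance-based spiking implementation of that hypothesis (cortical
  feature columns + a model VTA, three plastic pathways),
* the tabular TD(0)/TD($\lambda$) reference models it is contrasted with,
* a fixed random RNN demonstrating why an *untrained* recurrent network is
  not a repeatable temporal basis, and
* the spike-train metrics used to summarise all of them
  (sliding-criterion auROC, envelope/peak estimators, per-trial integrated
  dopamine).

# The spiking model

## Neurons and synapses

All neurons are conductance-based leaky integrate-and-fire units,

$$C\,\dot v_i = g_L(E_L - v_i) + g_{E,i}(E_E - v_i) + g_{I,i}(E_I - v_i)
  + \sigma,$$

with $C = 200$ pF, $g_L = 10$ nS, $E_L = -60$, $E_E = -5$, $E_I = -70$ mV,
spike thresholds $-55$ mV (excitatory) / $-50$ mV (inhibitory), reset to
$-61$ mV and an effective 3 ms refractory period.  Each presynaptic neuron
carries a saturating synaptic activation per connection class,

$$\dot s_i = -s_i/\tau_s + \rho\,(1 - s_i)\sum_k \delta(t - t_k^i),
  \qquad \rho = 1/7,$$

with $\tau_s$ = 80 ms (cortical excitatory), 20 ms (cortical inhibitory and
VTA excitatory) and 10 ms (VTA inhibitory).  Conductances are weighted sums
of presynaptic activations, $g_{\alpha,i} = \sum_j W^\alpha_{ij} s_j$, with
a 10 ms transmission delay between populations (one timestep within the
recurrent Timer pool).  Firing rates are estimated online by an exponential
filter with $\tau_r = 40$ ms.

**Numerical integration.**  The membrane equation is advanced by
*exponential integration conditional on the current conductances*:
$v \leftarrow v_\infty + (v - v_\infty)e^{-g_{tot}\Delta t/C}$.  This is
exact for piecewise-constant conductances and reduces to the closed-form
leak decay when synaptic input is zero.  The choice is forced: the
Inhibitory$\to$Messenger pathway is strong enough (hundreds of nS summed
over 100 synapses of $-20$ nS) that $g_{tot}\Delta t/C \gg 1$, where a
plain forward-Euler step oscillates and generates spurious spikes.
Synaptic activations, rate filters, eligibility traces and weight updates
remain forward Euler at $\Delta t = 1$ ms.

**Units.**  Everything is computed in mV, ms, nS, pF and pA — a mutually
consistent system (nS·mV = pA, pA·ms/pF = mV), so configuration values in
the field's customary units enter the integrator unchanged.  The published
noise terms carry no units; we interpret them as white-noise currents in pA
(so the cortical value $10^{-10}$ A reads as a 100 pA-scale fluctuation)
and treat their magnitudes, together with the tonic VTA drive, as
calibration constants (below).

## Architecture

Each conditioned stimulus has its own cortical column containing three
populations of 100 neurons: **Timers** (recurrently connected excitatory
cells whose persistent-firing duration is learned), a local **Inhibitory**
population, and **Messengers** (excitatory cells that fire at the end of
the Timer envelope).  The model VTA has 100 dopaminergic (**DA**) and 100
GABAergic (**GABA**) neurons.  Fixed weights (nS per synapse, all-to-all
unless noted): Timer$\to$Messenger 0.5, Inhibitory$\to$Messenger $-20$,
Timer$\to$Inhibitory 0.3, Messenger$\to$Inhibitory 1, GABA$\to$DA $-1.5$.
Stimuli are channels of 100 Poisson units pulsed at 30 Hz for 100 ms;
the reward channel projects sparsely (connection probability 0.1) onto DA
neurons.  That sparseness, shared by the plastic CS$\to$DA projection, is
what produces the heterogeneous single-neuron discriminability profiles
after learning.

Two wiring constants are this package's own additions, both documented
here because the published table does not itemise them:

* **Feed-forward inhibition** (`cs_i`): each stimulus channel also drives
  its column's Inhibitory population.  Without it the disynaptic
  Timer$\to$Inhibitory$\to$Messenger loop lags the direct
  Timer$\to$Messenger drive by two transmission delays, and the Messengers
  fire a large spurious burst at cue onset.  The default (0.8 nS) admits a
  small residual cue response — which in practice assists the recruitment
  of reward-time inhibition — while keeping the reward-time burst dominant.
* **Interneuron resting bias** (`tonic_i` = $-170$ pA): the column
  interneurons are biased so that they stop firing as soon as the Timer
  envelope ends, rather than tracking the slowly decaying Timer synaptic
  activation for a further ~100–200 ms.  This places the Messenger burst at
  the envelope end — i.e. at the expected reward time — which is what the
  architecture requires of Messengers.

## Reinforcement and plasticity

The signed reinforcement is computed from the population-mean DA rate
through a dead-band: $D(t) = r_{DA} - (r_0 - \theta)$ below the band,
$0$ inside, $r_{DA} - (r_0 + \theta)$ above, with $r_0 = 5$ Hz and
$\theta = 2$ Hz.  It is broadcast globally, as befits a diffusely released
neuromodulator.

Each plastic synapse carries two Hebbian-activated eligibility traces
(LTP- and LTD-associated) with the published constants: recurrent
$\tau^p/\tau^d = 1800/800$ ms, ceilings $3.0/3.3\times10^{-3}$, activation
rates $\eta^p/\eta^d = 300/135$; feed-forward $2000/800$ ms,
$1.5/4.0\times10^{-3}$, $650/40$.  Weight changes are competitive:
$\dot W = \eta D(t)\,(T^p - T^d)$.  Messenger$\to$GABA synapses use the
simpler dopamine-modulated Hebbian rule $\dot W = \eta D(t) r_i r_j$ (the
two-trace variant is available behind `m_gaba_dttl`); in cortex the
Hebbian term is divided by $1 + \alpha D(t)$ (floored at 0.1), restricting
cortical trace generation during large positive reinforcement.

**Hebbian operating regime.**  The rate products entering the trace
equations are normalised by a *Hebbian rate scale* (default 60 Hz).  This
single constant decides the fixed-point structure of the whole learning
rule, so it deserves its own paragraph.  Near saturation
($\eta H \gtrsim 10$ during sustained firing) both traces ride near their
ceilings, and because the LTD ceiling exceeds the LTP ceiling, coincident
reinforcement *depresses* active synapses; after activity ends the LTP
trace outlives the LTD trace (slower decay), so reinforcement arriving
~100–140 ms (recurrent) to several hundred ms (feed-forward) after offset
*potentiates*.  That sign reversal in time is what lets a delayed reward
teach Timers to lengthen toward — but not beyond — the reward, and lets
cue-evoked dopamine arrest the growth of its own feed-forward weights.  At
much smaller $\eta H$ the LTP trace dominates at all times and cue-evoked
dopamine becomes self-amplifying, with no fixed point short of the weight
cap.

**Learning-rate gains.**  The published per-pathway learning rates
($\eta_{rec} = 1.5\times10^{-4}$ ms$^{-1}$; per-synapse magnitudes
$|N(0, 1.5)|$ feed-forward and $|N(0, 10^{-2})|$ for Messenger$\to$GABA,
rectified so a sampled sign cannot invert the rule) are combined with
dimensionless pathway gains (defaults 30 / 0.4 / 0.6).  The gains absorb
the unit ambiguity between the printed rates, the Hz-scale reinforcement
and the dimensionless traces; they were fixed once so that the standard
30-trial protocol traverses its stages within those 30 trials, and are not
protocol-specific.

## Calibration

The tonic drive of the VTA populations is calibrated by bisection so that
the unstimulated DA and GABA populations fire at $5 \pm 0.25$ Hz — the
stated functional target — under their 120 pA noise.  GABA is calibrated
first (it receives no synaptic input at rest), then DA under the resulting
inhibitory tone; a single shared constant cannot hit both targets because
the two populations have different thresholds.  `calibrate_baseline()`
re-runs this procedure; the shipped defaults (30.3 / 68.4 pA) are its
output.

Initial weights: Timer recurrent weights start at 0.025 nS, giving a naive
persistent envelope of roughly 350–450 ms — a clear transient cue response
well short of the 1000 ms cue–reward delay; CS$\to$DA and
Messenger$\to$GABA start at zero, so the naive network responds to the
reward only.

# What a training session looks like

With the standard protocol (cue at 100 ms, reward at 1100 ms, 30 trials)
the session passes through the canonical stages: reward-only dopamine
(trial 1); rapid growth of the cue response while the reward response is
barely touched (trials ~3–10) — during which the per-trial integrated
reinforcement *exceeds* the naive reward-only integral, the signature that
separates this model from every TD variant; Timer envelope growth to the
cue–reward interval (trials ~8–16); and Messenger-driven suppression of
the reward response (trials ~12–30).  The suppressed state is maintained
by an active balance — trials in which the Messenger burst arrives early
produce a small dopamine dip that trims the learned inhibition — so
late-session reward responses fluctuate near zero rather than vanishing
identically.

```{r}
session <- trace_conditioning(seed = 1, n_trials = 30)
probe <- trace_conditioning(net = session$network, n_trials = 1,
                            learn = FALSE, seed = 99)
messenger_peak_time(probe$rates[, "CS1:M", 1])   # ~1100 ms
timer_duration(probe$rates[, "CS1:T", 1], threshold_fraction = 0.1)
```

The envelope duration estimator reports the time from cue onset until the
smoothed mean Timer rate last falls below a fraction (default 0.1) of its
peak; the low default reflects that the naive cue transient, not the
sustained plateau, sets the peak.  The Messenger peak estimator smooths
with a 50 ms window before taking the argmax.

# The TD reference models

The TD module is tabular TD($\lambda$) on a complete-serial-compound basis:
the cue triggers a chain of microstates (optionally Gaussian-smeared, 50 ms
default width on a 10 ms grid, like the reward signal); before cue onset no
state is active.  Updates are *batch-per-trial*: all RPEs of a trial are
computed against the value function at trial start and the accumulating
eligibility update is applied once at the trial end.  With $\lambda = 0$
this is exactly tabular TD(0).  Batch updating makes the undiscounted
conservation law exact — for $\gamma = 1$ the per-trial RPE sum telescopes
to the delivered reward mass, trial after trial, to machine precision —
whereas online within-trial updating drifts at $O(\alpha^2)$.  The
learning rate has no published value; the default (0.05) converges well
inside the simulated trial counts.

# The fixed-RNN counterexample

`simulate_rnn()` integrates $\tau_{net}\dot u = -u + W\phi(u) + I(t)$ with
$W_{ik} \sim N(0, g/\sqrt{K})$, $K$ = number of units (full connectivity),
logistic $\phi$ (tanh available), and a unique Gaussian input projection
per stimulus pulsed for 100 ms.  Defaults $n = 500$, $g = 1.5$ (rich
dynamics), $\tau_{net} = 50$ ms have no published values and are
exposed in the config.  Presenting A-B-C versus B-A-C and aligning at the
shared final stimulus yields strictly positive trajectory divergence while
identical runs diverge by exactly zero — an untrained recurrent network is
history-dependent and therefore not a repeatable basis.

# Analysis choices

The auROC of two spike-count samples slides an integer criterion from zero
to the maximum observed count, plots exceedance probability against
exceedance probability, appends the $(0,0)$ and $(1,1)$ endpoints and
integrates by trapezoid.  This construction is *identical* to the
Mann–Whitney $U$ statistic with the half-tie convention (the trapezoid over
a simultaneous drop contributes exactly half), which the tests verify
against a brute-force all-pairs oracle; no tie-handling discrepancy exists
between the two formulations.  Binned discriminability uses 50 ms bins and
25 trials per condition against a no-stimulus baseline session.

# Protocol-level choices

* Trials are independent: membrane, synaptic, rate and trace state reset at
  trial boundaries (traces last seconds at most); weights persist.  Each
  trial starts with a 200 ms unrecorded warm-up so tonic firing and the
  rate filters are settled at $t = 0$.
* Reward omission, extinction and blocking run on a trained network; the
  dip, the depression of cue weights and the absence of learning for an
  inserted second cue all follow from the same rules with no extra
  machinery.  Unblocking can be driven either by scaling the reward drive
  or by an additive exogenous offset to $D(t)$ (no mechanism for exogenous
  dopamine is prescribed; an additive offset is the minimal choice).
* Distractor events target their own column and, by default, fall in the
  post-reward window during training (their traces then never overlap
  reward-evoked reinforcement); the post-training probe places the
  distractor between cue and reward, where the suppressed reward response
  leaves nothing to reinforce it — the same reason an inserted cue is
  blocked.  A 15% relative tolerance on the final cue-evoked response
  defines "indistinguishable" for the paired clean/distractor comparison.
* The value-tracking variant computes a second neuromodulator $A(t)$ from a
  shadow DA population that receives the same excitatory drive as DA but
  only the *tonic* level of GABA inhibition, then drives the feed-forward
  updates with $A$ instead of $D$.  Because $A$ is never suppressed, the
  learned cue response scales with reward magnitude instead of converging
  to a magnitude-independent fixed point.
* Sequential conditioning uses 80 trials (the longer of the two published
  trial counts, which we map to the three-event protocol) with stage
  boundaries detected by rule — which event windows carry positive $D$ —
  not by fixed trial indices.

# Problem sizes in the shipped tests

The test suite runs the full 30-trial standard session once and shares it
across the interval-learning, convergence and integrated-reinforcement
checks; the auxiliary protocols (omission, extinction, blocking,
unblocking, distractors, sequential, value scaling) run at 8–20 trials
from shared trained networks,
which is enough to exhibit each sign/monotonicity outcome.  TD and RNN
checks use their full published settings (they cost seconds).  The
acceptance script re-runs the standard session at full size.

# Known limitations

* The cue–reward intervals this implementation can learn are bounded by
  the synaptic and eligibility time constants to a few seconds.
* The Timer envelope end is a noise-driven collapse, so its trial-to-trial
  jitter (±50–100 ms at the trained interval) is irreducible at these
  population sizes; the Messenger peak and the maintenance of reward
  suppression inherit that jitter.
* Unhoused parameters: the published table lists eligibility time
  constants $\tau_e, \tau_{ea} = 10, 20$ (in timestep units) that no
  equation references; they are carried as inert config entries
  (`tau_e`, `tau_ea`) for completeness.
* Columns do not interact except through dopamine; cross-column cortical
  wiring (and any emergence of the column microcircuit from random
  connectivity) is out of scope.
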