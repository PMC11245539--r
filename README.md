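# flexsim

Spiking-network simulation of reward-prediction learning with a *plastic*
temporal basis.

Temporal-difference (TD) models of dopaminergic reward-prediction error
assume that every cue comes with a pre-existing chain of temporal basis
functions spanning all possible cue–reward delays.  `flexsim` implements
the alternative: a conductance-based spiking network in which the temporal
basis itself is learned during conditioning.  Cortical feature columns of
leaky integrate-and-fire neurons contain **Timers** (recurrently connected
cells whose persistent-firing duration is plastic), a local **Inhibitory**
population, and **Messengers** (cells that fire at the end of the Timer
envelope).  A model VTA contains dopaminergic (DA) and GABAergic neurons
firing at a calibrated ~5 Hz baseline.  The signed reinforcement

```
D(t) =  r_DA(t) − (r0 − θ)   if r_DA ≤ r0 − θ
        0                    if r0 − θ < r_DA < r0 + θ      (r0 = 5 Hz, θ = 2 Hz)
        r_DA(t) − (r0 + θ)   if r_DA ≥ r0 + θ
```

gates three plastic pathways.  Timer→Timer and CS→DA synapses learn by
competitive two-trace eligibility learning,

```
τᵖ dTᵖ/dt = −Tᵖ + ηᵖ H (Tᵖmax − Tᵖ)        (likewise for the LTD trace Tᵈ)
dW/dt     = η D(t) (Tᵖ − Tᵈ)
```

where `H` is the Hebbian rate product (divided by `1 + αD(t)` in cortex);
Messenger→GABA synapses use the dopamine-modulated Hebbian rule
`dW/dt = η D(t) r_i r_j`.  Over a standard trace-conditioning session the
Timer envelope grows to span the cue–reward delay, a cue-evoked dopamine
response emerges *before* the reward response is suppressed, the per-trial
integrated release transiently exceeds the naive reward response — which no
TD variant can do — and the Messenger-driven inhibition finally cancels the
reward-evoked burst.

The package also ships the tabular TD(0)/TD(λ) reference models on a
complete-serial-compound basis, a fixed random RNN counterexample showing
that an untrained recurrent network is not a repeatable temporal basis,
preset protocols for reward omission, extinction, sequential conditioning,
blocking/unblocking, distractor robustness and value scaling, and the
sliding-criterion auROC spike-train discriminability analysis.  See the
methods vignette (`vignettes/flexsim-methods.Rmd`) for the full model, all
calibration constants and their rationale.

## A worked example

```r
library(flexsim)

session <- trace_conditioning(seed = 1, n_trials = 30)   # CS 100 ms, US 1100 ms
probe   <- trace_conditioning(net = session$network, seed = 99,
                              n_trials = 1, learn = FALSE)

messenger_peak_time(probe$rates[, "CS1:M", 1])
#> [1] 1103
timer_duration(probe$rates[, "CS1:T", 1], threshold_fraction = 0.1)
#> [1] 917
round(range(integrated_da(session)))
#> [1]  183 1864
```

The Messenger population of the trained network peaks at ~1.1 s — the
programmed reward time — and the Timer envelope spans roughly the 1000 ms
cue–reward delay: the network has internalised the interval.  The
integrated reinforcement per trial starts near the naive reward response
(~900 Hz·ms), transiently rises above it while the cue response grows, and
relaxes toward zero as the reward response is suppressed.  Compare the TD
reference, whose integrated RPE can never exceed its first-trial value:

```r
td <- run_td(td_config(gamma = 0.99, lambda = 0.975, n_trials = 100))
max(integrated_rpe(td)) <= integrated_rpe(td)[1]
#> [1] TRUE
```

A thin command-line wrapper over the same functions is installed at
`exec/flexsim` (subcommands `run`, `td`, `rnn-demo`, `analyze`,
`calibrate-baseline`).

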