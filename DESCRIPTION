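Package: flexsim
Title: Spiking-Network Simulation of Flexibly Learned Reward Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates a conductance-based spiking network in which plastic
    cortical temporal basis functions (Timer, Inhibitory and Messenger
    populations) co-evolve with dopaminergic reinforcement in a model ventral
    tegmental area during trace conditioning.  Learning uses competitive
    two-trace eligibility rules gated by a signed dopamine signal, together
    with a dopamine-modulated Hebbian rule for inhibitory recruitment.  Ships
    preset conditioning protocols (trace conditioning, reward omission,
    extinction, sequential conditioning, blocking/unblocking, distractor
    robustness, value scaling), tabular TD(0)/TD(lambda) reference models on a
    complete-serial-compound basis, a fixed random recurrent-network
    counterexample, and spike-train analysis metrics including
    sliding-criterion auROC discriminability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
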