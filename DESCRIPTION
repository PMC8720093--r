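Package: odrsim
Title: Closed-Loop Simulation of a Wearable Hypoxia-Triggered Opioid-Antidote Autoinjector
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale digital twin of a wearable opioid-overdose rescue
    device: a pneumatic needle-insertion and drug-delivery mechanism modeled
    as a gas-driven piston system with Hagen-Poiseuille needle flow, a
    pulse-oximetry-triggered dose controller that delivers up to three 1 ml
    antidote doses at 5-minute intervals when SpO2 falls to 90% or below,
    and a synthetic-physiology layer that generates the SpO2 traces the
    controller consumes, including an optional one-compartment antidote
    pharmacokinetic recovery model. Trajectories, traces and event logs are
    tibbles with plotting and tidier methods; scenario runs are fully
    reproducible from a configuration file and a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
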