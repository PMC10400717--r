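Package: neurogrow
Title: Agent-Based Simulation of Neural Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the development of neuronal morphologies as populations
    of interacting growth agents ("fronts") advancing over discrete cycles.
    Fronts are spheres (somata) or capsules (neurite segments) that extend,
    branch, migrate and retract under user-written growth rules, with strict
    collision avoidance accelerated by a uniform spatial grid. Includes soma
    migration with a leading filipodium and trailing axon, branch retraction,
    diffusible substrate cues with stochastic sensing, synapse formation with
    Hebbian weight updates, an event-sourced SQLite trace database with resume
    support, SWC morphology export, and a deterministic realisation of a
    shared-memory parallel scheduling design with partitioned private-section
    arrays and a two-stage grid lock broker.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
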