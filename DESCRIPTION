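Package: pumpneuron
Title: Conductance-Based Motoneuron Model with a Sodium-Dependent Na/K Pump
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a single-compartment Hodgkin-Huxley-type model of a
    Drosophila larval motoneuron with an electrogenic, sodium-dependent
    Na/K-ATPase pump current, a dynamic intracellular sodium concentration
    in a sub-membrane shell, and a sodium reversal potential that follows
    the Nernst equation. Three model variants toggle the sodium
    concentration and reversal potential between frozen and dynamic.
    Provides step, bidirectional-ramp, exponential-chirp (zap) and
    test-pulse stimulus protocols, an adaptive stiff integrator with a
    fixed-step Runge-Kutta cross-validation oracle, spike and burst
    detection, firing-rate and afterhyperpolarization metrics, and scripted
    in-silico experiments (FI curves, excitability-memory protocols, pump
    parameter sweeps, and bursting surveys).
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
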