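Package: crrtpta
Title: Monte Carlo Target-Attainment Simulation for Beta-Lactam Dosing
    during Continuous Renal Replacement Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates virtual critically ill patients receiving continuous
    renal replacement therapy (CRRT) and computes the probability of
    pharmacodynamic target attainment (PTA) for intermittently infused
    beta-lactam and carbapenem antibiotics. Patients are generated by
    truncated log-normal sampling of pharmacokinetic and CRRT parameters
    with rank-based weight correlations; free drug concentration-time
    profiles over 72 h follow a one-compartment, first-order, multiple-dose
    intermittent-infusion model with CRRT clearance given by sieving
    coefficient times delivered effluent flow. Attainment of fT>=MIC,
    fT>=4xMIC and 100%fT>=MIC targets is aggregated overall and by patient
    weight quartile, classified against the 90% optimality threshold, and
    exported as plain-text tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
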