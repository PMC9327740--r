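Package: warfarinCEA
Title: Cost-Effectiveness Modelling of Pharmacist-Managed Warfarin Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A nine-state, half-cycle-corrected Markov cohort model for the
    lifetime cost-utility comparison of pharmacist-managed warfarin therapy
    against standard anticoagulation care in patients with mechanical mitral
    valve prostheses, together with the trial endpoint machinery around it:
    the Rosendaal linear-interpolation time-in-therapeutic-range (TTR)
    statistic with NICE category binning, one-way (tornado) sensitivity
    analysis over every ranged model input, incremental cost-effectiveness
    summaries with dominance and WHO willingness-to-pay classification, and a
    seeded synthetic INR-trajectory generator that emulates monthly
    anticoagulation-clinic visits so the TTR and transition-probability
    machinery can be exercised and validated without patient-level trial
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
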