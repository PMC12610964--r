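Package: cattlemc
Title: Markov Chain Modelling and MCMC Simulation of Multi-Sensor Cattle
    Activity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models neck-sensor cattle activity records as a discrete-state
    Markov chain over six behavioural states (feeding, moving, lying,
    standing, rumination while standing, rumination while lying) and three
    environmental variables (temperature, humidity, temperature-humidity
    index). Provides readers and validators for aggregated activity tables,
    per-variable time-series feature extraction (mean, spread, shape,
    entropy, trend strength, linearity, curvature), PCA-based variable
    selection, transition-matrix estimation with stationary-distribution
    and n-step analysis, direct inverse-CDF chain simulation and
    Metropolis-Hastings sampling of a stationary target, AAE/AES/RMSE
    accuracy reporting, and a seeded synthetic-herd generator for
    end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
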