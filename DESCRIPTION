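Package: mothnav
Title: Moth-Inspired Odor Source Localization in Simulated Plumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop simulation of odor-source localization by a
    ground-running agent using moth-inspired navigation strategies. Implements
    the robust moth-inspired (RMI) controller, which switches between active
    and inactive search modes from the agreement of odor and wind detection
    directions and modulates translational and angular speed as a piecewise
    affine function of odor-detection frequency, together with the classical
    surge-zigzag-loop (SZL) and surge-cast (SC) baselines. Provides an
    intermittent Gaussian-filament plume model with Ornstein-Uhlenbeck wind,
    bilateral threshold odor sensing with a four-way body-frame wind direction
    class, unicycle trial and batch runners with the standard success-radius
    and timeout protocol, and evaluation tools: success rates, localization
    times, crosswind trajectory RMSE, Fisher exact comparison of success
    counts, frequency-binned behavioral modulation curves and piecewise-affine
    gain recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
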