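Package: tactstream
Title: Neuromechanistic Simulation of Audio-Tactile Auditory Stream Segregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bistable perception of ABA- tone sequences (the auditory
    streaming paradigm) with and without synchronized vibrotactile pulses, using
    a three-population firing-rate competition model with recurrent excitation,
    mutual inhibition, spike-frequency adaptation, synaptic depression and
    Ornstein-Uhlenbeck input noise, integrated by Euler-Maruyama. Provides
    tonotopic stimulus construction with exponential spread profiles, trial-level
    percept classification (integrated versus segregated), Monte-Carlo estimation
    of proportion-segregated across frequency-difference and tactile-condition
    grids, differential-evolution fitting of the spread-profile parameters to
    proportion data with repeat-fit uncertainty, a synthetic generator for binary
    behavioral reports under a mixed-logit model, and mixed-effects logistic
    analysis with odds-ratio and Cohen's d effect-size conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
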