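Package: protean
Title: Dynamic State Variable Models of Behavioral Unpredictability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying when behavioral unpredictability (residual
    within-individual variability in behavior) is favored by selection in
    foraging animals. Implements a discrete-time dynamic state variable
    model in which a forager's state drives both mortality and terminal
    reproduction: state-dependent per-step mortality curves (combined
    starvation plus mass-dependent predation, linear, or constant), a
    binomial one-step transition kernel whose spread encodes the level of
    behavioral unpredictability, and backward iteration over the foraging
    horizon yielding expected-fitness surfaces and the optimal
    unpredictability policy. Closed-form fitness surfaces for the
    no-dynamics (frozen) case provide independent validation, and a
    marginal-value-theorem patch-foraging Monte Carlo illustrates how
    unpredictable patch residence times inflate variance in foraging
    success over short horizons. A command-line interface exposes the
    model runs as reproducible, configuration-driven experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
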