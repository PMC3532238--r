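Package: sbnet
Title: Stochastic Boolean Networks for Gene Regulatory Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling gene regulatory networks as probabilistic
    Boolean networks (PBNs) and for simulating them as stochastic Boolean
    networks (SBNs), i.e. logic-gate networks operating on random bitstreams
    in which Boolean function selection is performed by stochastic
    multiplexers. Provides exact (analytic) and bitstream-estimated state
    transition matrices with and without random gene perturbation,
    deterministic-asynchronous updating, time-frame-expanded steady-state
    estimation, attractor and pseudo-attractor analysis, matrix difference
    norms, a random-network generator, a JSON network interchange format and
    a command-line interface. Includes the two-gene p53-Mdm2 network as a
    built-in example model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
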