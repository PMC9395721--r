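Package: memsurv
Title: Simulation of RRAM In-Memory-Computing Inference for Deep Cox
    Survival Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end design-flow simulator for running a DeepSurv-style
    deep Cox proportional-hazards network on resistive-memory (RRAM)
    crossbar arrays. Provides a calibrated generator of WHAS-like
    right-censored survival data, a feed-forward network trained by Cox
    partial likelihood with Harrell's concordance index, incremental
    network quantization (INQ) onto a 17-level differential conductance
    grid, behavioral statistical models of multilevel RRAM programming
    (ML-Set and ML-Hybrid) including conductance drift, Monte-Carlo
    simulation of analog matrix-vector-multiply inference on four 64x64
    crossbars, and analytic latency, throughput, power and energy figures
    of merit for the accelerator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
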