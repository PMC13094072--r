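Package: mantisstrike
Title: Strike Kinematics, Power Amplification and Spring-Model Analysis for
    Impaling Mantis Forelegs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the biomechanical analysis of ultrafast impaling
    predatory strikes driven by latch-mediated spring actuation (LaMSA).
    Computes joint-angle, angular-velocity and tip-speed time series from
    2-D landmark tracks exported by video motion tracking, segments the
    strike into a closed-joint plateau and a rapid sweeping phase, and
    summarizes peak kinematics. Processes force-transducer traces (baseline
    correction, peak and median extraction, body-mass-specific
    normalization) and estimates muscle-mass-specific mechanical power
    output by two declared approaches, issuing a power-amplification
    verdict against the direct-muscle performance range. Also generates
    Archimedean double-spiral spring geometry for physical spring models,
    and fits linear mixed-effects models (type x friction with per-sample
    random intercepts, type III tests, estimated marginal means, pairwise
    contrasts) to physical-model trial data. A synthetic-data module
    generates landmark tracks, force traces and model-trial studies with
    fully known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
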