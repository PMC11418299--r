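Package: aeroscope
Title: Intermittent-Flow Respirometry Metrics and Staged Inference for
    Fish Aerobic Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates and analyses intermittent-flow respirometry
    experiments on fish. Raw dissolved-oxygen traces are segmented into
    flush/measure cycles and converted to mass-specific oxygen uptake
    rates; resting metabolic rate is estimated as a low quantile of
    validated cycles, maximum metabolic rate by a sliding-window
    steepest-slope search, and excess post-exercise oxygen consumption by
    monotone-spline integration of the recovery curve. Companion tools
    compute somatic organ indices, percentage compact myocardium, venous
    oxygen plateaus and critical thermal maxima, and a staged statistical
    workflow (normality and homoscedasticity gates with log10 fallback,
    factorial ANOVA with an automated interaction drop rule,
    repeated-measures linear mixed models with BIC selection, and
    Tukey-adjusted contrasts with letter displays). A synthetic cohort
    generator with known ground truth makes every stage testable
    end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    emmeans,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
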