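Package: let7cycle
Title: Coupled Let-7 / Cell-Cycle / Malignant-Transformation Network Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model coupling the cyclin/Cdk cell-cycle
    oscillator to an inflammation-driven malignant-transformation switch
    through the microRNA Let-7, which sequesters cyclin, IL6 and Ras mRNAs
    into translationally inactive complexes (a ceRNA sponge). Provides
    segment-wise stiff integration with piecewise-constant perturbation
    schedules, dynamical-regime classification (quiescence, proliferative
    limit-cycle oscillations, endocycle-like dynamics), one- and
    two-parameter regime maps, the CPI and NTSI proliferation/transformation
    indexes computed from trajectories or from tumor/non-tumor expression
    matrices, heterogeneous cell-population simulation with uniform
    parameter jitter, one-at-a-time sensitivity analysis, and a synthetic
    tumor-cohort generator for testing the index pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
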