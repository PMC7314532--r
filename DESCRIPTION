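Package: ecsdiff
Title: Extracellular-Space Diffusion Analysis for Real-Time Iontophoresis and Dopamine Volume Transmission
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing diffusion in brain extracellular space (ECS).
    Implements the point-source diffusion model with first-order uptake used in
    real-time iontophoresis (RTI) experiments with tetramethylammonium (TMA+),
    the inverse problem recovering ECS volume fraction (alpha), tortuosity
    (lambda) and nonspecific uptake (k') from concentration-time curves, the
    cohort-level two-way ANOVA with layer pooling, a seeded synthetic-cohort
    generator for parameter-recovery studies, a method-of-lines solver for the
    spherically symmetric dopamine reaction-diffusion equation with
    Michaelis-Menten uptake under control and alcohol-exposed ECS geometries,
    and the microglial ramification (dendritic-density) index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
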