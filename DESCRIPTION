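Package: ternarySAR
Title: Ternary-Complex Equilibrium Modeling and Degradation SAR for
    Heterobifunctional Degraders
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative toolkit linking PROTAC-induced ternary-complex
    formation to targeted protein degradation. Implements the three-body
    binding equilibrium with cooperativity (exact numeric solution and
    closed-form SPR-limit approximations, including the hook effect), a
    rapid-equilibrium model of the target ubiquitination initial rate with
    its linear and saturation regimes, reduction of surface plasmon
    resonance sensorgrams (1:1 Langmuir kinetics, steady-state affinity,
    ternary-complex half-life), cellular degradation metrics (percent of
    control, four-parameter logistic DC50/Dmax, trapezoid AUC, one-phase
    decay half-life and initial degradation rate), correlation-based
    structure-activity analysis over compound tables, and geometric
    scoring of candidate ternary-complex structures (clash counting,
    center-of-geometry and principal-axis model pruning, Kabsch RMSD,
    Shrake-Rupley solvent-accessible surface area and buried surface
    area). Seeded synthetic-data generators for every input format make
    the full pipeline testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
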