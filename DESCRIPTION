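Package: foamfem
Title: Explicit Finite-Element Toolkit for Hyperelastic Foam Soft Tissue
    with Contraction-State Stiffness Scaling and Strain-Based Injury Metrics
Version: 0.1.0
Authors@R:
    person("foamfem", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Desk-scale computational machinery for studying how volumetric
    muscle and soft-tissue stiffness affects impact response and predicted
    injury. Implements a hyperelastic, compressible, Ogden-type foam material
    driven by engineering stress-strain load curves with ordinate scaling
    (SFO) and strain-rate tables; a minimal explicit-dynamics finite-element
    solver (8-node solid elements, lumped mass, central-difference time
    integration, CFL-critical time step with selective mass scaling, rigid
    plane penalty contact); post-processing of element time histories into
    effective (von Mises) stress, effective strain, accumulated effective
    plastic strain and linear-fit Young's moduli; and strain-based injury
    criteria (failed-element volume, cumulative strain damage measure) plus
    force-based risk-curve lookup. Includes deterministic test fixtures and a
    reader/writer for a small keyword-deck subset.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
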