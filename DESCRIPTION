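Package: g4hydro
Title: Geometry and Hydrodynamics of DNA G-Quadruplexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Geometric and hydrodynamic analysis of G-quadruplex nucleic
    acid structures. Reads atomic coordinate files and SAXS dummy-atom bead
    models, computes backbone and glycosidic torsion angles with syn/anti
    classification and bulge-specific range flagging, detects guanine
    tetrads from Hoogsteen hydrogen-bond geometry and classifies their
    shape from simple base-pair parameters, measures stacking twist and
    channel-ion spacing, and derives scattering and hydrodynamic
    descriptors (radius of gyration, pair-distance distribution, maximum
    dimension, Kirkwood and Rotne-Prager-Yamakawa hydrodynamic radii,
    sedimentation coefficient, frictional ratio, molecular mass from
    atomic composition). Includes buffer standardization of sedimentation
    coefficients, infinite-dilution extrapolation of sedimentation
    velocity species series, and synthetic generators (ideal parallel
    quadruplexes, analytic sphere bead models, simulated sedimentation
    series) so the full analysis chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, bio3d, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
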