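Package: gcoupler
Title: G-Protein Coupling Selectivity of Class A GPCRs from TM5/TM6 Helix
    Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts primary Gs versus Gi/o coupling of activated class A
    G-protein-coupled receptors from the cytosolic geometry of transmembrane
    helices 5 and 6. Extracts helix descriptors (TM5 length, TM5 tilt,
    TM6 length, TM6 outward movement) from atomic structures placed in a
    common membrane frame by Kabsch superposition, with helix orientations
    estimated from averaged backbone carbonyl vectors. Provides the
    standardization + PCA projection with its closed-form decision boundary
    (Gs when the first principal coordinate exceeds 0.7), a bagged
    class-weighted decision-stump forest with stratified cross-validation and
    classification metrics, buried-interface-area analysis between extended
    TM segments and the G-protein alpha subunit via Shrake-Rupley solvent
    accessible surface area, and an ideal-helix synthetic-structure
    generator so the whole pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
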