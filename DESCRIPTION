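Package: glucotriage
Title: Multiparameter Lead Triage and Glucose-Homeostasis Analysis for
    DPP-4 Inhibitor Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a multi-stage lead-triage
    pipeline for beta-amino-acylhydrazone DPP-4 inhibitor candidates:
    structure-derived physicochemical descriptors (Ertl TPSA, molecular
    weight, H-bond donors), a molecular lipophilicity potential field,
    the logP/hydration-free-energy relation, a six-attribute
    multiparameter-optimization (MPO) desirability score with violation
    reporting, rule-based ADMET/PAMPA triage flags, docking-pose
    validation (affinity-energy and symmetry-aware RMSD gates) with
    residue-level interaction profiling, and in-vivo glucose-homeostasis
    statistics (GTT percent reductions and baseline-corrected AUC, ITT
    Kitt, glycogen fold changes, qPCR 2^-ddCt, MTT viability). Seeded
    synthetic-data generators with known ground truth stand in for
    predictor outputs and animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
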