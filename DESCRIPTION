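Package: allokin
Title: Binding-Mode Annotation and Pose Evaluation for Allosteric Kinase Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating and evaluating kinase-ligand complexes by
    binding modality. Implements geometric Type I/I1/2/II/III/IV binding-mode
    classification from region-resolved ligand contacts, KLIFS-residue pocket
    fingerprinting with PCA centroid assignment, ligand diversity analysis
    (Morgan-class fingerprints, Butina clustering, Shannon index),
    physiological-pH hydrogen and charge correction, dataset curation
    operators (time split, deduplication, stratified selection, MD frame
    filtering), binding-mode-resolved docking-pose evaluation
    (symmetry-corrected RMSD, centroid distance, Wilson intervals), and the
    deterministic mathematics of a tempered diffusion perturbation schedule
    with a beta-distributed time sampler. Synthetic fixture generators make
    every component testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    Biostrings
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
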