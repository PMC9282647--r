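Package: hergsift
Title: Structure-Based hERG Liability Classification from Docking Scores
    and Protein-Ligand Interaction Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-docking workflow for structure-based classification of
    hERG (Kv11.1) channel binders versus nonbinders. Curates ChEMBL-style
    bioactivity tables into thresholded binder/nonbinder datasets, converts
    docked protein-ligand poses into per-residue nine-bit interaction
    fingerprints (SIFt-style, OR-merged over the four channel monomers),
    trains L1-regularised linear support vector machines on docking scores
    alone or fused with fingerprints, evaluates them with a 100-repeat
    balanced resampling protocol, extracts docking-score decision
    thresholds, and ranks binding-site residues by Kolmogorov-Smirnov
    occurrence counts. Includes a synthetic-data generator (toy tetrameric
    receptors, controlled ligand poses, planted statistical structure) so
    the full pipeline runs without external downloads or docking engines.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
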