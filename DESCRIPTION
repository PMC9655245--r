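Package: dualscreen
Title: Dual-Target Ligand- and Structure-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filter-ensemble classification models for ligand-based virtual
    screening against two targets (acetylcholinesterase peripheral-site and
    beta-secretase inhibitors), with Matthews-correlation scored filters and
    per-molecule indexes; dataset curation with Tanimoto-diversity pruning and
    property-matched decoy dilution; docking-pose interaction profiling
    (hydrogen bonds and van der Waals contacts against pre-determined residue
    lists); receptor-structure selection by true/false-positive enrichment;
    and weighted combination of ligand and docking scores for candidate
    selection. Includes synthetic-fixture generators with exact ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
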