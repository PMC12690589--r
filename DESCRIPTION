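Package: segrmsf
Title: Segment-Resolved Ensemble RMSF Analysis of Structural Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies positional variability across heterogeneous
    structural ensembles (molecular-dynamics trajectories, AI-generated
    conformer sets, multi-model experimental structures) with a
    segment-resolved, fixed-reference root-mean-square-fluctuation
    statistic (eRMSF). The ensemble is partitioned into contiguous frame
    segments of a user-chosen size and, for every atom, residue or
    region, the RMS deviation from one fixed reference structure is
    computed per segment, yielding a groups-by-segments fluctuation
    matrix, an average per-group profile, and a structure annotated with
    fluctuation values in the B-factor column. Includes Kabsch
    least-squares superposition, an atom-selection mini-language,
    readers for PDB/DCD/XTC ensembles, seeded synthetic-ensemble
    generators with known fluctuation structure, ggplot2 heatmap and
    profile renderers, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
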