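Package: structgroups
Title: Grouping, Alignment Tracks and Superposition for Protein Structure Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Organizes mixed collections of experimentally determined protein
    structures and computed structure models into groups, and summarizes each
    group in sequence and in three dimensions. Entities are clustered by
    sequence identity with a greedy centroid algorithm at multiple thresholds,
    assembled into groups by deposition batch, shared reference accession, or
    cluster membership, and summarized with faceted histograms that support
    subgroup filtering. A reference-anchored group alignment carries positional
    tracks: consensus and variation, modeled and unmodeled regions, per-residue
    prediction confidence (pLDDT), CA-geometry secondary structure, domain and
    ligand binding-site frequencies, and mutation markers. Group members can be
    superposed rigidly onto a reference with an alignment-guided Kabsch fit,
    optionally restricted to an alignment column range. A synthetic fixture
    generator builds structures with ideal secondary-structure geometry, hinge
    motions, ligand placements, unmodeled gaps and confidence profiles for
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
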