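Package: trajscape
Title: Comparative Conformational-Dynamics Analysis of MD Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analyzes molecular-dynamics conformational ensembles of
    membrane receptors (and proteins generally) with a set of local,
    comparative metrics: an exponential-contact surface-topography score
    that grades concavity and convexity per atom and per residue, a local
    side-chain (or backbone) flexibility statistic computed after optimal
    superposition of each residue's reference-frame environment,
    persistence-weighted polar and nonpolar interaction networks from
    distance-only contact criteria, and conformational substates from a
    spherically constrained density-based clustering of the pairwise
    C-alpha RMSD matrix. Includes static structure-comparison tools
    (optimal superposition, inter-structure domain rotation angles, ligand
    contact shells, minimum distances), a synthetic-ensemble generator
    with planted ground truth for validation, and a report pipeline that
    runs all metrics from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
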