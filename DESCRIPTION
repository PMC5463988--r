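Package: protchem
Title: Compositional and Thermodynamic Analysis of Differential Protein Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemical-composition metrics for proteomes and thermodynamic
    potential diagrams for proteomic transformations. Computes the average
    oxidation state of carbon (ZC) and the per-residue water and oxygen demand
    of proteins by stoichiometric projection onto basis species (QEC, QEC+, or
    inorganic bases), compares up- and down-expressed protein groups from
    differential-expression studies (group means, Wilcoxon tests, common
    language effect sizes), evaluates per-residue chemical affinities of
    protein formation over grids of oxygen fugacity and water activity,
    summarizes them as weighted rank-difference potential diagrams with
    equipotential contours, and solves a lipid-protein redox mass balance.
    Includes a seeded synthetic-data generator for up/down protein groups with
    controllable shifts in mean ZC and water demand.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
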