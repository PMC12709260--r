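Package: idplens
Title: Conformational-Ensemble Analysis for Intrinsically Disordered Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes conformer ensembles of intrinsically disordered
    peptides by radius of gyration and computes, per group and globally,
    the standard solution-scattering and structural observables: Debye
    forward SAXS with Cromer-Mann form factors and excluded-solvent
    contrast, Guinier and dimensionless Kratky analyses, indirect-transform
    pair-distance distributions P(r), chi-square agreement with
    experimental curves, Shrake-Rupley solvent accessibility, minimal
    C-alpha contact and hydrogen-bond occupancy maps, Kabsch-Sander
    secondary-structure assignment, Ramachandran region fractions, Karplus
    scalar J-couplings, circular-dichroism unit conversion and basis-set
    prediction, time-lagged independent component analysis, free-energy
    landscapes, and GROMOS (Daura) conformational clustering. A seeded
    Markov-chain generator over backbone dihedral basins produces
    reproducible, autocorrelated multi-replica ensembles with tunable
    compaction, so the whole pipeline is testable without molecular
    dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
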