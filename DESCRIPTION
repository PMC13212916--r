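Package: nucpack
Title: Sugar-Pucker-Dependent Nucleoside Rotamer Libraries and
    Nucleotide Repacking on Rigid Backbones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives nucleoside rotamer libraries from glycosidic
    torsion (chi) statistics using Gaussian mixture models with BIC
    model selection, optionally conditioned on the sugar pseudorotation
    class (2'-endo-like versus 3'-endo-like).  The libraries drive a
    side-chain-packing engine that rebuilds and redesigns nucleotides
    (including their sequence identity) on a rigid nucleic-acid
    backbone via dead-end elimination and Monte Carlo/simulated
    annealing.  Includes torsion-based conformational descriptors
    (endocyclic torsions, pseudorotation phase and amplitude, chi),
    model-quality metrics (pooled side-chain RMSD, chi recovery rate,
    interaction network fidelity, lDDT, fraction of native contacts),
    and deterministic synthetic-fixture generators for furanose rings,
    single nucleotides and idealized duplexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
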