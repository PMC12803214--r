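Package: hdxlc
Title: Differential Hydrogen-Deuterium Exchange and PLIMSTEX Analysis of
    Protein Kinetic Stabilizers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of differential hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) experiments that probe small-molecule kinetic
    stabilization of proteins, developed around immunoglobulin light-chain
    stabilizer pharmacology. Provides back-exchange-corrected percent
    deuteration from centroid masses using maximally deuterated controls,
    reduction of peptide-level deuteration to single-residue resolution on a
    shared sequence alignment, stabilizer-versus-vehicle difference maps and
    exchange-curve area summaries, PLIMSTEX ligand-titration fitting with a
    unimolar (one ligand per dimer) protection model reporting baseline
    uptake, maximal protection and EC50, and limited-proteolysis kinetics
    (exponential decay fits, trapezoidal areas, single-timepoint protection,
    Pearson comparisons). A forward simulator generates realistic synthetic
    experiments (EX2 exchange under per-residue protection factors,
    ligand-coupled protection, isotopic envelopes, back exchange, centroid
    noise) so that every analysis stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    minpack.lm,
    pracma,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'hdxlc-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io.R'
    'intrinsic-rates.R'
    'simulate.R'
    'exchange.R'
    'residue.R'
    'plimstex.R'
    'proteolysis.R'
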