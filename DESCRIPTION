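Package: diazoSIP
Title: Single-Cell Stable-Isotope-Probing Rates and Mass Balance for
    Diazotroph-Diatom Symbioses
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates single-cell N2- and CO2-fixation rates and carbon-based
    growth rates from nanoSIMS isotope-ratio measurements of host-symbiont
    pairs, partitions fixed nitrogen and carbon between a diatom host and its
    intracellular diazotrophic symbionts by element mass balance, scales
    per-symbiosis rates to volumetric rates with exact Poisson confidence
    intervals on microscopy census counts, computes bulk isotope-incorporation
    rates from incubation endpoints, and calls genome presence in metagenomes
    from breadth-of-coverage statistics. A seeded forward simulator of
    symbioses, incubations and ion-counting noise makes every stage testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'isotope-core.R'
    'mass-balance.R'
    'census-scaling.R'
    'bulk-rates.R'
    'diazoSIP-package.R'
    'genome-detect.R'
    'synthetic-data.R'
    'io.R'
    'pipeline.R'
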