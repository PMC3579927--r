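Package: vsbench
Title: Virtual-Screening Benchmark Construction and Validation Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating structure-based virtual-screening
    benchmarks against a flexible receptor, together with the enzyme-kinetics
    models used to characterize hits. Implements property-matched decoy
    selection by an iterative per-active "decoy score" (physicochemical
    descriptor differences plus the complement of a shape/pharmacophore
    comboscore), an alignment-free USR-style comboscore reference provider,
    active-recovery curves with truncated (early-recognition) AUC, ensemble
    score aggregation and two-program rank consensus, Kabsch superposition and
    gromos RMSD clustering for selecting receptor conformations from a
    trajectory, dose-response (IC50) and uncompetitive/mixed inhibition
    fitting, and seeded synthetic-data generators for every input the
    pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
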