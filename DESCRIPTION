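Package: molmutbench
Title: Benchmarking Molecular Mutation Operators for Evolutionary Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking framework for molecular mutation operators used in
    evolutionary de novo design. Implements five mutation strategies (graph-edit,
    corpus-trained graph-edit, reaction-template, SELFIES-token and SMILES-token
    mutation) evaluated under a standardized mutant-budget protocol for validity,
    computational cost, bioactivity conservation, complexity shift and structural
    diversity. Includes a self-contained molecular toolkit (SMILES parsing and
    sanitization, canonicalization, a restricted SELFIES codec, circular
    fingerprints, a reaction-SMARTS subset engine), topological complexity
    indices, fingerprint-based random-forest QSAR scoring, and population
    diversity analytics (Tanimoto similarity, descriptor PCA, histogram
    Kullback-Leibler divergence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    igraph
SystemRequirements: OpenBabel (obabel on the PATH; ChemmineOB is the
    in-process fallback)
Config/testthat/edition: 3
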