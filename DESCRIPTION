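Package: cddap
Title: Virtual DNA-Encoded Library Design from a Compact Diazide Scaffold
Version: 0.1.0
Authors@R:
    person("cddap", "maintainers", email = "cddap@example.org",
           role = c("aut", "cre"))
Description: Builds and characterises virtual DNA-encoded libraries (DELs)
    assembled from the compact diazide scaffold
    3-azido-5-(azidomethyl)benzoic acid. Provides building-block curation
    (desalting, rule-of-2 filtering, Morgan-fingerprint k-means diversity
    selection), reaction-scheme-driven enumeration of the four library
    architectures (organocatalytic enolate [3+2] cycloaddition, CuAAC,
    azide reduction, amidation), drug-likeness profiling (Lipinski
    rule-of-5 violation counts and QED), UMAP chemical-space embedding with
    kernel-density occupancy analysis against a reference compound
    population, synthetic data generators, and a pipeline driver.
    Molecular mechanics (SMILES handling, descriptors, fingerprints,
    reaction application, UMAP) are delegated to a bundled batch-mode
    Python/RDKit worker; all analysis logic is implemented in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
SystemRequirements: Python (>= 3.9) with rdkit and umap-learn importable
    from the interpreter named by option 'cddap.python' (default "python").
Config/testthat/edition: 3
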