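Package: midcontext
Title: Isotopologue Detection, MID Correction, and Labeling-Similarity
    Networks for Stable-Isotope Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Instrument-agnostic tools for stable-isotope labeling
    experiments starting from feature-intensity tables: non-targeted
    detection of isotopologue groups by tracer mass differences and
    labeled-versus-unlabeled intensity-pattern tests, mass isotopomer
    distribution (MID) calculation with natural-abundance correction
    against the unlabeled condition via non-negative least-squares
    deconvolution, labeling filters, MS1 accurate-mass adduct annotation
    against a user-supplied compound table, reference-standard and MS2
    spectral matching, and contextualization of unknown metabolites
    through MID-similarity networks with Cytoscape JSON export and
    reference-pathway overlay. A forward simulator of labeling
    experiments makes the whole pipeline testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
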