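Package: ftcbuild
Title: Functional Therapeutic Chemical Classification of Drug Modes of Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a Functional Therapeutic Chemical (FTC) classification:
    mode-of-action categories ("Pro-X agent" / "Anti-X agent") are generated
    from the biological-process and molecular-function terms of a GO-style
    ontology, and approved drugs are assigned to them by composing the sign of
    each drug-target perturbation with the (signed) regulatory involvement of
    the target in a process or function. Includes parsers for OBO, GAF and
    tab-separated drug-target/ATC tables, a rule-based classifier with a
    brute-force oracle, taxonomy construction, Jaccard mode-of-action
    similarity with a within-ATC-class permutation test, precision/recall
    evaluation against curated ATC equivalences, and seeded synthetic
    knowledge-base generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
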