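Package: searchdev
Title: Objective Development and Validation of Literature Search Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the empirically guided ("objectively derived")
    development and validation of Boolean search strategies for systematic
    reviews. Reads bibliographic records in MEDLINE flat-file (.nbib) and RIS
    formats, computes per-term document frequencies and sensitivities in a
    development set versus a database population sample, aggregates controlled
    vocabulary over subheadings, screens candidate terms by frequency
    thresholds, parses and evaluates Ovid-style numbered-line search
    strategies against a local corpus, assembles candidate terms into a
    strategy reaching full development-set recall, validates the strategy on a
    held-out reference set, and emits a standardized documentation bundle.
    Includes a seeded synthetic-corpus generator with known term-planting
    probabilities so the whole pipeline can be exercised without database
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
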