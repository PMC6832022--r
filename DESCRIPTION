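Package: viromicro
Title: Viral Scaffold Classification and Codon-Level Microdiversity for
    Marine Viromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing assembled virome metagenomes: identification
    of bona fide viral scaffolds by the added-viral-quotient (AVQ) score over
    pVOG-style orthologous-group hits, protein baiting and manual curation;
    closest-relative taxonomic affiliation and consensus virus-host
    prediction from homology, CRISPR-spacer and shared-tRNA signals;
    mapped-read relative abundance profiles with Shannon diversity; and
    codon-resolved microdiversity from read pileups, including filtered
    variant calls, percentage of polymorphic sites and pN/pS ratios against
    a neutral single-substitution expectation. Includes a seeded synthetic
    community and read simulator with controlled variant frequencies and
    selection strength so every stage can be validated against a known
    truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
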