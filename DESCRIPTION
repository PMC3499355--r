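Package: combevol
Title: Parallel Evolution of Protein Domain Combinations on Species Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed binary domain-combination repertoires per genome
    from Pfam-style domain annotations (HMMER3 domtblout or a generic hit
    table), reconstructs ancestral presence/absence of combinations on a
    rooted species tree by unweighted (Fitch/Hartigan) parsimony and of
    individual domains by Dollo parsimony, counts independent origins of
    each combination, and derives clade-specific and core repertoires,
    per-genome parallel-evolution ratios, and LCA-normalized rates of
    independent emergence. Includes a synthetic gain/loss evolution
    simulator with a complete truth log so the whole pipeline is testable
    without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
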