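Package: mirem
Title: Prioritizing miRNAs from Gene Sets by Hypergeometric Filtering
    and Expectation-Maximization
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies and ranks candidate microRNAs (miRNAs) likely to
    drive an observed gene-expression signature.  Given a list of
    differentially expressed genes and one or more miRNA-target
    prediction databases, the package unifies gene identifiers, builds a
    user-selected view of the target compendium (union or
    intersection-of-k databases, optionally conserved interactions
    only), filters candidate miRNAs by an upper-tail hypergeometric
    over-representation test with Benjamini-Hochberg correction, and
    then re-scores the surviving candidates with an
    expectation-maximization algorithm that softly partitions each gene
    among the miRNAs predicted to target it, so that overlapping target
    predictions are down-weighted.  Predicted miRNAs are additionally
    clustered by their 6-nt seed regions to flag duplicated
    (seed-identical) predictions.  Includes a synthetic-data generator
    for spike-in benchmarking and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
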