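Package: tripdist
Title: Triplet-Based Quantification of Gene-Tree Incongruence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies topological discordance between gene trees and
    multigenic (species) trees using rooted leaf triplets. Tabulates triplet
    resolution frequencies over bootstrap forests, applies a strict
    majority-retention rule, and computes triplet fit dissimilarities between
    a reference tree and a forest and between pairs of forests. Identifies
    triplets of the reference tree strongly rejected by a pooled bootstrap
    collection with a two-cell chi-squared frequency test and tallies
    per-taxon involvement. Maps loci along chromosome arms by integrating an
    exponential recombination-intensity gradient (cM/Mb) into genetic
    distances, and tests whether incongruence tracks recombination with rank
    correlations, quadratic regression, and within-arm permutation tests.
    Includes a synthetic-data generator (random-join species trees,
    NNI-perturbed gene trees, noisy bootstrap forests) so the whole pipeline
    is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
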