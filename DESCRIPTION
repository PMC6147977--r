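Package: phagekit
Title: Phage Pan-Genome Phylogenomics, Growth Kinetics, and Phage-Antibiotic Synergy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing lytic bacteriophages computationally:
    ortholog clustering of phage proteomes into gene families, pan-genome
    summaries (core, accessory, singleton genes), presence/absence Jaccard
    distances with neighbor-joining dendrograms, and co-grouping consensus
    trees over single-copy core-gene trees; estimation of burst size, latent
    period, and adsorption kinetics from one-step growth and adsorption
    assays; host-range summaries from spot assays; and analysis of
    plate-reader OD590 growth/kill curves for phage-antibiotic combination
    (synergy) testing via end-OD and trapezoid AUC statistics with one-tailed
    t-tests. A mechanistic synthetic-data generator (bacteria, Erlang-staged
    phage infection, Hill-type antibiotic kill, resistant subpopulations)
    makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    igraph,
    mclust,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
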