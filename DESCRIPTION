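Package: pancora
Title: Pan- and Core-Genome Evolutionary Analysis of Bacterial Genome Sets
Version: 0.1.0
Authors@R:
    person("Pancora", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to partition bacterial pan-genomes into core, softcore,
    shell and cloud gene classes, and to study the evolutionary structure of
    clade-structured genome collections. Includes orthologous-family
    delimitation by Markov clustering of a gated protein-similarity graph,
    gene-count quality filtering, randomized rarefaction curves with
    open/closed pan-genome calls, average-identity clade clustering with
    Gower distances, per-gene neighbor-joining trees under the Jukes-Cantor
    model with nodal-distance screening against a reference topology,
    consensus-based SNP and clade-diagnostic (eco)SNP detection, a
    presence-based horizontal gene transfer screen, and functional-category
    enrichment with Fisher's exact test. A synthetic pan-genome simulator
    with planted, recoverable ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    ape,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
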