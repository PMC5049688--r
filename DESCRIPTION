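Package: bacsim
Title: Coalescent Simulation of Bacterial Genomes with Gene-Conversion
    Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Whole-genome simulator of bacterial evolution under the
    coalescent with gene conversion. Generates ancestral recombination
    graphs for circular or linear, entire or fragmented genomes, with
    both within-species recombination (modelled as ARG splits) and
    between-species recombination (divergence injected into the imported
    tract from the root-homologous sequence). Recombination events are
    sampled analytically so that only events effectively altering
    ancestral material are generated, which makes high recombination
    rates tractable. Outputs include Jukes-Cantor sequence alignments,
    the clonal frame, per-segment local genealogies, recombination event
    lists and Graphviz renderings of the ARG. Includes independent
    brute-force and rejection-sampling reference implementations used to
    validate the analytical sampler, and a harness for measuring
    clonal-frame recovery accuracy of phylogenetic methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
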