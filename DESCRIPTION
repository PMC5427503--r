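Package: TetradRecomb
Title: Tetrad-Based Meiotic Recombination Mapping and Crossover
    Interference Statistics for Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses genome-wide meiotic recombination in
    Saccharomyces cerevisiae tetrads. Provides a synthetic tetrad generator
    (gamma-renewal interfering plus Poisson noninterfering crossovers and
    gene-conversion tracts with known ground truth), an event caller that
    annotates crossovers, noncrossovers and gene-conversion tracts from
    four-spore SNP segregation tables, crossover interference statistics
    (one-pathway gamma maximum likelihood, two-pathway gamma-mixture EM with
    one shape fixed at 1, coefficient of coincidence on 25 kb genome bins,
    chromatid interference), the Poisson obligate-crossover model for
    nonexchange (E0) chromosomes, per-chromosome descriptive summaries, and
    classical tetrad genetics (Perkins map distances, spore-based distances,
    spore-viability tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
biocViews: Genetics, Recombination, Sequencing, Software
RoxygenNote: 7.3.3
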