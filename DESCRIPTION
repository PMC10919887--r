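Package: zwturnover
Title: Forward-Time Simulation of Sex-Determining Mutation Turnover on
    Undifferentiated ZW Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of the microevolution of a
    single-gene sex determiner on an undifferentiated ZW chromosome pair.
    A chromosome carrying a fully functional copy of the gene acts as W;
    any loss-of-function change (missense, nonsense, or splice-site
    disruption) converts it to Z, so sex determination is an emergent
    property of the locus model. Recombination between homologs is
    suppressed in proportion to their divergence. The package classifies
    point mutations against an annotated gene model, censuses fixed and
    segregating loss-of-function mutations at the end state, detects
    turnover of the sex-determining position, and computes diversity
    statistics (pi, dxy, Fst) together with the small association tests
    used to validate a sex-linked variant (genotypic chi-square,
    heterogamety-pattern classification, sex-ratio test, windowed
    nucleotide diversity, and male/female depth log-ratios). A synthetic
    data module generates gene models with valid exon/intron structure,
    sex-genotype cohorts under female heterogamety, and coverage tracks,
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
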