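Package: haplopop
Title: Population Genetics of Multilocus MHC Haplotypes in Bottlenecked
    Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing adaptive genetic variation at a
    haplotype-coded major histocompatibility complex (MHC) marker against a
    panel of neutral microsatellites in small, serially founded populations,
    motivated by the conservation genetics of the crested ibis (Nipponia
    nippon). Provides rule-based phasing of two-locus MHC diplotypes
    (unambiguous, pedigree and frequency tiers) with an EM cross-check and
    parentage verification, linkage-disequilibrium tests, within-population
    diversity statistics (unbiased expected heterozygosity, rarefaction
    allelic richness, heterozygosity-excess bottleneck test under the
    stepwise mutation model), hierarchical AMOVA with a grouping search,
    Hedrick's standardized G'ST with bootstrap neutral envelopes and outlier
    calls, chord-distance neighbour-joining trees, Nei-Gojobori dN/dS
    selection tests on antigen-binding-site partitions, and a forward-in-time
    founder-effect simulator that generates genotypes, pedigrees and truth
    haplotypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
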