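Package: fuzzmap
Title: Graphical Genotyping and Fine Mapping of a Recessive Locus in
    Backcross Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reusable pipeline for mapping a monogenic recessive trait in a
    first-backcross (BC1) population, modelled on the workflow used to map the
    peach fruit-skin hairiness (G) locus: screening of parent-informative
    homozygous differential SNPs from VCF genotypes, graphical genotyping of
    donor introgression fragments via a bin map, genotype-phenotype
    co-segregation scanning, recombinant-based interval narrowing with marker
    panels, candidate-gene and variant filtering against GFF3 gene models, and
    a recessive-model marker-assisted-selection (MAS) genotyper. Includes a
    BC1 population simulator (Haldane crossover model, configurable genotyping
    error and missingness) so that every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
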