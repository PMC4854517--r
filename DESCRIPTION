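Package: poolscan
Title: Pool-Seq Scans for Loci Under Ecological Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pool sequencing (pool-seq) population-genomics toolkit for
    detecting loci under ecological selection from pooled allele read
    counts: per-SNP chi-square differentiation scans between superpools
    with coverage normalisation, clustering of significant SNPs into
    independent loci on gap-rescaled coordinates, environmental
    (salinity) correlation and a binomial mixed-model contrast of
    spawning groups, window diversity statistics (pooled heterozygosity,
    Tajima's D, nucleotide diversity within and between populations, LD
    decay), F_IT mixture tests for the Wahlund effect, neighbor-joining
    trees from allele-frequency distances, annotation-category
    enrichment of allele-frequency differences, read-depth window ANOVA
    for copy-number variants, and a single-site coalescent simulator of
    the allele-frequency spectrum. Includes a synthetic metapopulation
    generator with a machine-readable truth table so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    lme4,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
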