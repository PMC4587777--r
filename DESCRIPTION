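Package: autozygmap
Title: Autozygosity Mapping and Recessive Variant Prioritization in
    Consanguineous Pedigrees
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for mapping autosomal-recessive disease genes in
    consanguineous families. Simulates pedigrees with identity-by-descent
    tracking (gene dropping with Haldane recombination), computes Wright's
    inbreeding coefficient by path counting, calls runs of homozygosity
    (ROH) from biallelic SNP genotypes as surrogates of autozygosity,
    intersects autozygomes across affected individuals to nominate shared
    founder haplotypes, and applies an ordered variant-prioritization
    cascade (frequency, zygosity, autozygome position, consequence,
    predictor consensus) with segregation checking. Reads and writes
    PLINK PED/MAP, VCF, BED and TSV.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
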