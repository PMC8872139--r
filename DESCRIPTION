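Package: digenicBSA
Title: Digenic Segregation Analysis, Recombinant Fine Mapping, and
    Bulked-Segregant Delta SNP-Index Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for map-based cloning of recessive plant mutants.
    Enumerates two-locus epistasis models (duplicate recessive and
    relatives) to derive expected F2 and F2:3 segregation ratios and
    test observed counts by chi-square goodness of fit; counts
    recombination events among mutant individuals across ordered
    markers to delimit mapping intervals; computes pooled SNP indices
    from allele depths, applies GATK-style hard filters, and runs a
    sliding-window delta SNP-index scan to call candidate regions;
    intersects intervals with gene annotations, classifies coding
    variants at codon level, applies differential-expression
    thresholds, and ranks candidate genes by combined evidence. A
    synthetic-data generator produces segregating populations,
    near-isogenic bulk pools, toy gene models, and expression tables
    with truth records for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    vcfR,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, VariantAnnotation, Sequencing
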