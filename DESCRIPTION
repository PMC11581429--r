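Package: famscreen
Title: Family-Based Rare-Variant Screening for Mendelian Lupus
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A forward genetic screen for multiplex families with systemic
    lupus erythematosus: call-quality filtering of exome variant calls,
    gene-level prioritization with the gene damage index (GDI) and the
    mutation significance cutoff (MSC), allele-level filtering by the
    CADD/MSC deleteriousness ratio and population allele frequencies,
    inheritance-model candidate detection (autosomal dominant, autosomal
    recessive homozygous and compound heterozygous with trans-phasing,
    X-linked) with pedigree segregation checks, PCA-based nearest-neighbour
    ancestry assignment against a labelled reference panel, and the
    quantification formulas used downstream of the screen (autoantigen
    array Ab Scores and the TIRF actin clearance ratio). A synthetic-data
    module generates multiplex pedigrees with Mendelian transmission,
    planted causal genotypes, Balding-Nichols structured reference panels
    and antigen-array matrices so the whole pipeline is testable without
    access to confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Genetics, VariantDetection, SNP, Software
RoxygenNote: 7.3.3
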