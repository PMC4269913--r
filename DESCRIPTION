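Package: pedforge
Title: Validated Reformatting of Pedigree and Genotype Data for Genetic
    Analysis Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests family-based and case/control genetic study data in
    LINKAGE, annotated, PLINK (text and binary), and VCF formats; runs
    structural, Mendelian, allele-frequency, and Hardy-Weinberg
    error-checking stages; applies recoding, subsetting, omission, and
    pedigree-restructuring transforms; and writes analysis-ready file sets
    for LINKAGE, PLINK, Merlin, SOLAR, Eigenstrat, Structure, and FBAT.
    Genotypes for biallelic markers are held in a memory-efficient 2-bit
    packed matrix over typed individuals only.  A batch-file driven
    pipeline and a gene-dropping simulator with controlled defect
    injection make every stage reproducible and testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
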