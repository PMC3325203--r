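Package: RohBurden
Title: Runs of Homozygosity, Autozygosity Burden, and ROH Mapping
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detection of runs of homozygosity (ROH) from SNP genotype
    data, estimation of the genomic inbreeding coefficient Froh and its
    length- and frequency-based decompositions, case/control autozygosity
    burden analysis with per-dataset logistic and mixed-effects logistic
    models, and bin-level ROH association mapping with permutation-derived
    genome-wide significance thresholds. Includes a multi-dataset synthetic
    cohort simulator with planted autozygous tracts following the
    exponential (Haldane) tract-length model, genotype quality control and
    LD pruning, and PED/MAP, VCF and BED input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    lme4,
    jsonlite,
    yaml,
    vcfR,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
biocViews: SNP, GenomeWideAssociation, StatisticalMethod, Genetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
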