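Package: apiscan
Title: Windowed Population-Genomic Statistics, Selective-Sweep Scans and
    Wing Geometric Morphometrics for Honeybee Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for desk-scale population-genomic and morphometric
    analysis of resequenced honeybee (Apis cerana) cohorts: VCF genotype
    ingestion with missingness and minor-allele-frequency filtering,
    sliding-window nucleotide diversity and Weir-Cockerham Fst, pairwise
    Fst matrices and their summaries, per-individual heterozygosity and
    inbreeding coefficients, linkage-disequilibrium decay from genotype
    dosages, genotype PCA, a joint Z(Fst) x log2 theta-pi-ratio
    selective-sweep scan with region merging and gene overlap, TPS
    landmark I/O, centroid size, Generalized Procrustes Analysis with GLS
    consensus shapes, shape PCA, one-way ANOVA with LSD post-hoc letters,
    and stepwise regression of wing size on geography.  A Balding-Nichols
    genotype simulator and a landmark simulator provide ground-truth data
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
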