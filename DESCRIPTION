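Package: polyArray
Title: SNP Array Design and Genotype-Cluster Analysis for Allo-Polyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for designing SNP genotyping arrays in allo-polyploid
    crops whose subgenomes collapse onto a single diploid reference during
    short-read alignment. Implements discovery pipelines for di-allelic
    SNPs, multi-allelic SNPs, small indels and three classes of
    ploidy-reducing "haploSNPs" (marker SNPs coupled to fixed homoeologous
    sequence variants that destabilise off-target probe hybridisation);
    probe tiling and probeset accounting with flank, 16-mer and
    score screens; a two-channel genotype-cluster model across
    effective ploidy levels with quality classification (PHR, NMH, OTV,
    MHR, CRBT), the HomRO diploid-likeness statistic and off-target-variant
    recalling; pedigree-concordance and read-count binomial validation of
    genotype calls; and a fully seeded synthetic allo-octoploid panel
    generator (reference, gene models, per-accession VCFs, read depths,
    intensities, pedigrees) with ground-truth tables so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
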