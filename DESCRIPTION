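Package: tetrapop
Title: Population Genetics of Autotetraploid SNP Dosage Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the molecular characterization of autotetraploid
    breeding collections genotyped with SNP dosage arrays. Covers marker
    quality control (minor-allele-frequency and call-rate filtering,
    diploidization of tetraploid calls, ploidy inference from five-cluster
    genotype frequencies), per-marker and per-clone diversity statistics
    (expected and observed heterozygosity, polymorphic information content,
    inbreeding coefficients, nucleotide diversity, Watterson's theta and
    Tajima's D), population structure (Nei's 1972 genetic distance, Ward
    dendrograms with duplicate and mislabel curation, K-means/BIC selection
    of the number of clusters, discriminant analysis of principal components
    with cross-validation and discriminating-marker selection, pairwise
    Weir-Cockerham Fst), selection-signature scans (PCA-based outlier test
    with genomic-control correction, iHS and XP-EHH extended-haplotype
    statistics, Storey q-values, multi-method sweep consensus and gene-window
    lookup), distance-based core-collection selection, and pedigree
    verification (trio conflict rates, pedigree-based additive relationship
    versus marker-based genomic covariance). A synthetic-data generator
    produces structured tetraploid panels, pedigreed crosses and sweep
    haplotype panels with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    ape,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
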