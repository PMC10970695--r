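Package: binQTL
Title: Bin-Marker Linkage Mapping and QTL Detection from Low-Coverage F2
    Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping qualitative and quantitative trait loci in
    biparental F2 populations genotyped by low-coverage whole-genome
    resequencing. Implements SNP quality filtering, sliding-window bin
    genotype calling with breakpoint detection, bin-marker linkage map
    construction with EM estimation of recombination fractions, inclusive
    composite interval mapping (ICIM) with permutation-based LOD
    thresholds and LOD-drop support intervals, candidate-gene interval
    annotation with variant-effect classification, and relative expression
    analysis of candidate genes by the 2^-ddCt method. A fully
    parameterised F2 population simulator with ground-truth crossovers,
    genotypes and a planted dominant locus supports power studies and
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
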