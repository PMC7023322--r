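Package: sweepscan
Title: Windowed Selection-Signature Scans from Population Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting genomic signatures of selection between two
    populations from a multi-sample VCF of biallelic SNPs.  Implements
    sliding-window nucleotide diversity, Weir-Cockerham fixation index,
    Tajima's D, the top-percentile intersection decision rule with Tajima's D
    validation, runs-of-homozygosity detection (PLINK-style sliding-window
    algorithm), linkage-disequilibrium decay curves, identity-by-state
    distances with neighbor-joining trees, and a two-population genotype
    simulator (Balding-Nichols background plus planted selective sweeps) for
    end-to-end validation of the scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
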