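Package: methDeconv
Title: Tumor Purity and Differential Methylation from a Single Bisulfite
    Methylome
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates tumor purity (the mixing fraction of two cell
    populations) and per-population CpG methylation levels from a single
    tumor bisulfite-sequencing sample, with no matched normal. Reads are
    collected into 300 bp bins and each bin's read set is modelled as a
    two-component mixture over binary CpG methylation vectors, fitted by
    expectation-maximization. Informative bins are selected by bootstrap
    parameter stability, filtered for recurrent copy-number regions and
    CpG-island redundancy, and vote for the genome-wide minor-component
    fraction; differentially methylated bins and regions are then called
    at the fixed voted fraction. A synthetic read-mixture simulator with
    known truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: DNAMethylation, Epigenetics, Sequencing,
    DifferentialMethylation, Coverage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
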