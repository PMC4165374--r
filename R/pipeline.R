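## One reproducible run: extract -> purity -> DMR, with file outputs.

.write_purity_json <- function(est, config, path) {
  jsonlite::write_json(list(
    alpha1_hat = est@alpha1, n_informative = est@nInformative,
    bandwidth = est@bandwidth, qc = est@qc,
    config = unclass(config)), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}

.write_dmr_bed <- function(dmrs, path) {
  if (length(dmrs)) {
    dmrs$name <- sprintf("DMR_%d", seq_along(dmrs))
    dmrs$score <- as.integer(round(dmrs$mean_diff * 1000))
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(dmrs)),
      start = GenomicRanges::start(dmrs) - 1L,
      end = GenomicRanges::end(dmrs),
      name = dmrs$name, score = dmrs$score, strand = ".",
      n_bins = dmrs$n_bins, mean_diff = dmrs$mean_diff,
      direction = dmrs$direction)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    file.create(path)
  }
  invisible(path)
}

#' Run the full deconvolution pipeline
#'
#' Orchestrates read-call extraction (from a read-call table, or SAM plus
#' reference FASTA), genome tiling and binning, purity voting and DMR
#' calling, writing a machine-readable run directory: \code{purity.json},
#' \code{bin_fits.tsv}, \code{informative_bins.tsv}, \code{dmrs.bed} and
#' \code{log.txt}. Deterministic given \code{config$seed}. If the purity
#' stage finds too few informative bins, the error (class
#' \code{"insufficientInformativeBins"}) propagates after being logged.
#'
#' @param tablePath Read-call TSV (alternative to \code{samPath}).
#' @param samPath,fastaPath SAM alignments and reference FASTA
#'   (alternative to \code{tablePath}).
#' @param chromSizes Named vector of chromosome lengths, or a path to a
#'   two-column chrom-sizes file. Required with \code{tablePath}; derived
#'   from the FASTA otherwise.
#' @param cpgIslandBed,cnaBed Optional BED paths for CpG islands and
#'   recurrent CNA regions.
#' @param config A \code{\link{deconvConfig}}.
#' @param outDir Output directory (created).
#' @return Invisibly, a list with \code{purity}
#'   (\linkS4class{PurityEstimate}), \code{binFits}, \code{dmbs},
#'   \code{dmrs} and the output paths.
#' @export
runPipeline <- function(tablePath = NULL, samPath = NULL, fastaPath = NULL,
                        chromSizes = NULL, cpgIslandBed = NULL,
                        cnaBed = NULL, config = deconvConfig(),
                        outDir = tempfile("methdeconv_run_")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logp <- file.path(outDir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logp,
                               append = TRUE)
  logline("methDeconv run, seed %d", config$seed)
  if (!is.null(tablePath)) {
    if (is.null(chromSizes))
      stop("'chromSizes' is required with a read-call table")
    reads <- loadReadCallTable(tablePath)
    cpg_sites <- NULL
  } else if (!is.null(samPath) && !is.null(fastaPath)) {
    reads <- extractReadVectors(samPath, fastaPath)
    cpg_sites <- S4Vectors::metadata(reads)$cpg_sites
    if (is.null(chromSizes)) {
      ref <- Biostrings::readDNAStringSet(fastaPath)
      chromSizes <- stats::setNames(Biostrings::width(ref),
                                    sub("\\s.*$", "", names(ref)))
    }
  } else {
    stop("supply either 'tablePath' or both 'samPath' and 'fastaPath'")
  }
  if (is.character(chromSizes) && length(chromSizes) == 1L)
    chromSizes <- readChromSizes(chromSizes)
  logline("reads loaded: %d", nrow(reads))
  islands <- if (is.null(cpgIslandBed)) GenomicRanges::GRanges()
             else rtracklayer::import(cpgIslandBed, format = "BED")
  cna <- if (is.null(cnaBed)) GenomicRanges::GRanges()
         else rtracklayer::import(cnaBed, format = "BED")
  ann <- GenomeAnnotation(cpgIslands = islands, cnaRegions = cna,
                          chromSizes = chromSizes)
  bins <- tileBins(chromSizes, config$binSize)
  binned <- assignReadsToBins(reads, bins, cpgSites = cpg_sites)
  logline("bins: %d total, %d with reads", length(bins),
          sum(binned@bins$coverage > 0))
  est <- withCallingHandlers(
    tryCatch(estimatePurity(binned, ann, config),
             insufficientInformativeBins = function(e) {
               logline("purity stage failed: %s", conditionMessage(e))
               stop(e)
             }),
    condition = function(c) invisible(NULL))
  logline("alpha1_hat = %.3f from %d informative bins", est@alpha1,
          est@nInformative)
  .write_purity_json(est, config, file.path(outDir, "purity.json"))
  utils::write.table(est@informative,
                     file.path(outDir, "informative_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  qb <- qualifyingBins(binned, minCpG = config$minCpG,
                       minCov = config$minCov)
  fits <- fitAllBins(qb, est@alpha1, tol = config$tol,
                     maxIter = config$maxIter)
  het <- flagHeterogeneousBins(qb)
  fits$flag_variable <- het$flagged[match(fits$bin_id, het$bin_id)]
  utils::write.table(fits, file.path(outDir, "bin_fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dmbs <- callDMBs(fits, threshold = config$dmbThreshold)
  dmrs <- mergeDMBs(dmbs)
  .write_dmr_bed(dmrs, file.path(outDir, "dmrs.bed"))
  logline("DMBs: %d; DMRs: %d", nrow(dmbs), length(dmrs))
  invisible(list(purity = est, binFits = fits, dmbs = dmbs, dmrs = dmrs,
                 outDir = outDir))
}
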