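## Informative-bin selection and purity voting.
##
## Bins whose two fitted components are stable under read resampling carry
## genuine mixture signal; their per-bin minor fractions vote (by kernel
## density mode) for the genome-wide mixing ratio.

#' Default pipeline configuration
#'
#' Collects every tunable threshold with its default: 300 bp bins, strict
#' \code{minCpG} 10, read-count coverage 10, 50 bootstrap resamples, sd(m1)
#' threshold 0.1, top 500 bins, 1000 bp CNA flank, DMB difference threshold
#' 0.5, at least 500 informative bins, KDE bandwidth 0.02. Two eligibility
#' guards accompany the sd ranking: a bin's bootstrap fits must keep mean
#' component separation |m1 - m2| above \code{minComponentSep} (collapsed
#' fits carry no mixture signal) and a mean minor fraction of at least
#' \code{minAlphaVote} (the method cannot resolve contamination under 5
#' percent).
#'
#' @param binSize,minCpG,minCov,nBoot,sdThreshold,topN,cnaFlank,
#'   dmbThreshold,minInformative,minAlphaVote,minComponentSep,bandwidth,
#'   tol,maxIter,seed See description; any may be overridden.
#' @return A named list with class \code{"DeconvConfig"}.
#' @export
deconvConfig <- function(binSize = 300L, minCpG = 10L, minCov = 10L,
                         nBoot = 50L, sdThreshold = 0.1, topN = 500L,
                         cnaFlank = 1000L, dmbThreshold = 0.5,
                         minInformative = 500L, minAlphaVote = 0.05,
                         minComponentSep = 0.2, bandwidth = 0.02,
                         tol = 1e-6, maxIter = 500L, seed = 1L) {
  cfg <- list(binSize = as.integer(binSize), minCpG = as.integer(minCpG),
              minCov = as.integer(minCov), nBoot = as.integer(nBoot),
              sdThreshold = sdThreshold, topN = as.integer(topN),
              cnaFlank = as.integer(cnaFlank), dmbThreshold = dmbThreshold,
              minInformative = as.integer(minInformative),
              minAlphaVote = minAlphaVote,
              minComponentSep = minComponentSep, bandwidth = bandwidth,
              tol = tol, maxIter = as.integer(maxIter),
              seed = as.integer(seed))
  num <- vapply(cfg, is.numeric, logical(1))
  stopifnot(all(num), all(unlist(cfg[num]) >= 0))
  class(cfg) <- "DeconvConfig"
  cfg
}

#' Bootstrap the EM parameters of one bin
#'
#' Draws \code{nBoot} resamples of the bin's reads with replacement, fits
#' the free-\eqn{\alpha} mixture to each (dual deterministic starts, labels
#' normalized so \eqn{\alpha_1 \le 0.5}) and summarizes the spread of the
#' converged parameters. Resamples with fewer than two distinct reads are
#' redrawn (up to \code{maxRetries}); if a draw cannot be completed the bin
#' is flagged \code{failed}. Uses the current R random-number state, so
#' results are reproducible under \code{set.seed()}.
#'
#' @param X A bin's read set (see \code{\link{mixtureLogLik}} for accepted
#'   forms).
#' @param nBoot Number of resamples (default 50).
#' @param tol,maxIter EM settings.
#' @param maxRetries Redraw limit per resample.
#' @return A list with \code{n_boot}, standard deviations \code{sd_m1},
#'   \code{sd_m2}, \code{sd_alpha1}, means \code{mean_alpha1} and
#'   \code{mean_sep} (mean |m1 - m2|), the raw parameter matrix
#'   \code{params}, and \code{failed}.
#' @export
bootstrapBin <- function(X, nBoot = 50L, tol = 1e-6, maxIter = 500L,
                         maxRetries = 10L) {
  cc <- .as_counts(X)
  r <- cpp_bootstrap_bin(cc$M, cc$l, as.integer(nBoot), tol,
                         as.integer(maxIter), as.integer(maxRetries))
  if (r$failed)
    return(list(n_boot = as.integer(nBoot), sd_m1 = NA_real_,
                sd_m2 = NA_real_, sd_alpha1 = NA_real_,
                mean_alpha1 = NA_real_, mean_sep = NA_real_,
                params = r$params, failed = TRUE))
  p <- r$params
  list(n_boot = as.integer(nBoot),
       sd_m1 = stats::sd(p[, "m1"]), sd_m2 = stats::sd(p[, "m2"]),
       sd_alpha1 = stats::sd(p[, "alpha1"]),
       mean_alpha1 = mean(p[, "alpha1"]),
       mean_sep = mean(abs(p[, "m1"] - p[, "m2"])),
       params = p, failed = FALSE)
}

.summary_frame <- function(binned, summaries) {
  gr <- binned@bins
  data.frame(
    bin_id = gr$bin_id, chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    coverage = gr$coverage, n_cpg = gr$n_cpg,
    sd_m1 = vapply(summaries, `[[`, numeric(1), "sd_m1"),
    sd_m2 = vapply(summaries, `[[`, numeric(1), "sd_m2"),
    sd_alpha1 = vapply(summaries, `[[`, numeric(1), "sd_alpha1"),
    mean_alpha1 = vapply(summaries, `[[`, numeric(1), "mean_alpha1"),
    mean_sep = vapply(summaries, `[[`, numeric(1), "mean_sep"),
    failed = vapply(summaries, `[[`, logical(1), "failed"),
    stringsAsFactors = FALSE)
}

.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

#' Remove bins in (flanked) recurrent copy-number regions
#'
#' Amplified regions over-represent tumor reads and bias the local mixing
#' ratio, so any bin overlapping a CNA interval extended by \code{flank} bp
#' on both sides is dropped before voting.
#'
#' @param x A \linkS4class{BinnedReads} or a summary data.frame with
#'   \code{chrom}, \code{start}, \code{end}.
#' @param cnaRegions \code{GRanges} of recurrent CNA intervals.
#' @param flank Flank in bp (default 1000).
#' @return \code{x} with offending bins removed.
#' @export
filterCNA <- function(x, cnaRegions, flank = 1000L) {
  if (length(cnaRegions) == 0) return(x)
  grow <- GenomicRanges::trim(suppressWarnings(cnaRegions + flank))
  if (is(x, "BinnedReads")) {
    hit <- IRanges::overlapsAny(x@bins, grow, ignore.strand = TRUE)
    return(new("BinnedReads", bins = x@bins[!hit], reads = x@reads[!hit],
               qc = c(x@qc, list(cna_filtered = sum(hit)))))
  }
  hit <- IRanges::overlapsAny(.as_granges(x), grow,
                                    ignore.strand = TRUE)
  x[!hit, , drop = FALSE]
}

#' Keep at most one bin per CpG island
#'
#' Among bins overlapping the same CpG island, only the one with the
#' smallest bootstrap sd(m1) is kept (ties resolve to the leftmost); bins
#' overlapping no island pass through. Guards against sample-specific copy
#' number events not in the CNA list dominating the vote.
#'
#' @param summaries Bootstrap summary data.frame (from
#'   \code{\link{estimatePurity}}'s internals; must have \code{chrom},
#'   \code{start}, \code{end}, \code{sd_m1}).
#' @param cpgIslands \code{GRanges} of CpG islands.
#' @return The filtered summary data.frame.
#' @export
dedupeByIsland <- function(summaries, cpgIslands) {
  if (length(cpgIslands) == 0 || nrow(summaries) == 0) return(summaries)
  hit <- GenomicRanges::findOverlaps(.as_granges(summaries), cpgIslands,
                                     select = "first")
  keep <- rep(TRUE, nrow(summaries))
  for (isl in unique(hit[!is.na(hit)])) {
    rows <- which(!is.na(hit) & hit == isl)
    if (length(rows) < 2) next
    sd <- summaries$sd_m1[rows]
    sd[is.na(sd)] <- Inf
    best <- rows[order(sd, summaries$start[rows])][1]
    keep[setdiff(rows, best)] <- FALSE
  }
  summaries[keep, , drop = FALSE]
}

#' Select informative bins by bootstrap stability
#'
#' Informative bins are those whose bootstrap sd of the minor-component
#' methylation level is below \code{sdThreshold}, ranked ascending by that
#' sd and truncated to \code{topN}. Eligibility additionally requires a
#' non-collapsed fit (mean |m1 - m2| > \code{minSep}) and a mean minor
#' fraction of at least \code{minAlpha}. With fewer than
#' \code{minInformative} eligible bins an error of class
#' \code{"insufficientInformativeBins"} is raised: the sample may be pure,
#' or the contamination is less than 5\%.
#'
#' @param summaries Bootstrap summary data.frame.
#' @param sdThreshold Upper bound on sd(m1) (default 0.1).
#' @param topN Number of bins kept (default 500).
#' @param minInformative Minimum eligible bins before erroring (default
#'   500).
#' @param minAlpha,minSep Eligibility guards (see
#'   \code{\link{deconvConfig}}).
#' @return The selected rows, ordered by ascending sd(m1).
#' @export
selectInformative <- function(summaries, sdThreshold = 0.1, topN = 500L,
                              minInformative = 500L, minAlpha = 0.05,
                              minSep = 0.2) {
  ok <- !summaries$failed & !is.na(summaries$sd_m1) &
    summaries$sd_m1 < sdThreshold &
    !is.na(summaries$mean_sep) & summaries$mean_sep > minSep &
    !is.na(summaries$mean_alpha1) & summaries$mean_alpha1 >= minAlpha
  n_ok <- sum(ok)
  if (n_ok < minInformative) {
    stop(errorCondition(
      sprintf(paste0("insufficient informative bins (%d found, %d ",
                     "required): the sample may be pure, or the normal ",
                     "cell contamination is less than 5%%"),
              n_ok, minInformative),
      n_found = n_ok,
      class = c("insufficientInformativeBins", "error", "condition")))
  }
  sel <- summaries[ok, , drop = FALSE]
  sel <- sel[order(sel$sd_m1, sel$start), , drop = FALSE]
  utils::head(sel, topN)
}

#' Vote the sample-wide minor fraction
#'
#' Places a Gaussian kernel of bandwidth \code{bandwidth} on every per-bin
#' minor-fraction vote, evaluates the density on a \code{gridStep} grid
#' over \eqn{(0, 0.5]} and returns the mode.
#'
#' @param votes Numeric vector of per-bin minor-fraction votes (each bin's
#'   mean bootstrap \eqn{\alpha_1}).
#' @param bandwidth Kernel bandwidth (default 0.02).
#' @param gridStep Evaluation grid step (default 0.001).
#' @return A \linkS4class{PurityEstimate} (with empty \code{informative}
#'   table; \code{\link{estimatePurity}} fills it).
#' @examples
#' alpha1(voteAlpha(rep(0.30, 100)))   # 0.30
#' @export
voteAlpha <- function(votes, bandwidth = 0.02, gridStep = 0.001) {
  stopifnot(length(votes) > 0, all(is.finite(votes)))
  grid <- seq(gridStep, 0.5, by = gridStep)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm((g - votes) / bandwidth)) / bandwidth, numeric(1))
  new("PurityEstimate", alpha1 = grid[which.max(dens)],
      nInformative = length(votes), votes = as.numeric(votes),
      bandwidth = bandwidth,
      density = data.frame(alpha1 = grid, density = dens),
      informative = data.frame(), qc = list())
}

#' Estimate sample purity from binned reads
#'
#' Full informative-bin pipeline: keep qualifying bins, drop (flanked) CNA
#' regions, bootstrap every remaining bin, keep at most one bin per CpG
#' island, select the most stable bins, and vote the genome-wide minor
#' fraction by density mode. Deterministic given \code{config$seed}.
#'
#' @param binned A \linkS4class{BinnedReads} (qualifying filter is applied
#'   internally).
#' @param annotation A \linkS4class{GenomeAnnotation} (CpG islands and CNA
#'   regions; either may be empty).
#' @param config A \code{\link{deconvConfig}}.
#' @return A \linkS4class{PurityEstimate}; raises
#'   \code{"insufficientInformativeBins"} when the sample looks pure.
#' @export
estimatePurity <- function(binned, annotation = GenomeAnnotation(),
                           config = deconvConfig()) {
  set.seed(config$seed)
  qc <- list(bins_in = length(binned@bins))
  qb <- qualifyingBins(binned, minCpG = config$minCpG,
                       minCov = config$minCov)
  qc$qualifying <- length(qb@bins)
  qb <- filterCNA(qb, annotation@cnaRegions, flank = config$cnaFlank)
  qc$after_cna_filter <- length(qb@bins)
  summaries <- lapply(qb@reads, function(x)
    bootstrapBin(x, nBoot = config$nBoot, tol = config$tol,
                 maxIter = config$maxIter))
  sm <- .summary_frame(qb, summaries)
  qc$bootstrap_failed <- sum(sm$failed)
  sm <- dedupeByIsland(sm, annotation@cpgIslands)
  qc$after_island_dedupe <- nrow(sm)
  sel <- selectInformative(sm, sdThreshold = config$sdThreshold,
                           topN = config$topN,
                           minInformative = config$minInformative,
                           minAlpha = config$minAlphaVote,
                           minSep = config$minComponentSep)
  qc$informative <- nrow(sel)
  est <- voteAlpha(sel$mean_alpha1, bandwidth = config$bandwidth)
  est@informative <- sel[, c("bin_id", "chrom", "start", "end", "sd_m1",
                             "sd_m2", "sd_alpha1", "mean_alpha1")]
  est@qc <- qc
  est
}
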