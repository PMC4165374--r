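## Differential methylation at the voted mixing ratio: with alpha1 fixed,
## every qualifying bin is refit (dual starts), bins with a large
## between-component difference become differentially methylated bins
## (DMBs), and book-ended same-direction DMBs merge into regions (DMRs).

.direction <- function(m1_hat, m2_hat) {
  ifelse(m1_hat > m2_hat, "minor_hyper",
         ifelse(m1_hat < m2_hat, "minor_hypo", "undetermined"))
}

#' Fit every bin at a fixed minor fraction
#'
#' Runs the dual-initialization fixed-\eqn{\alpha} fit
#' (\code{\link{fitBinDualInit}}) on each bin of a
#' \linkS4class{BinnedReads}, producing per-component methylation levels.
#' Bins whose fit fails are skipped with a message.
#'
#' @param binned A \linkS4class{BinnedReads} (typically already filtered to
#'   qualifying bins).
#' @param alpha1 Fixed minor fraction, usually \code{alpha1(estimatePurity(...))}.
#' @param tol,maxIter EM settings.
#' @return data.frame with one row per fitted bin: coordinates,
#'   \code{m1_hat}, \code{m2_hat}, \code{diff} (= |m1_hat - m2_hat|),
#'   \code{direction}, \code{loglik}, \code{converged}.
#' @export
fitAllBins <- function(binned, alpha1, tol = 1e-6, maxIter = 500L) {
  stopifnot(alpha1 > 0, alpha1 <= 0.5)
  gr <- binned@bins
  n <- length(gr)
  m1h <- m2h <- ll <- rep(NA_real_, n)
  conv <- rep(NA, n)
  for (i in seq_len(n)) {
    x <- binned@reads[[i]]
    if (!length(x$M)) next
    fit <- tryCatch(
      fitBinDualInit(x, fixAlpha = alpha1, tol = tol, maxIter = maxIter),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("bin ", gr$bin_id[i], ": fit failed, skipped")
      next
    }
    m1h[i] <- m1(fit); m2h[i] <- m2(fit)
    ll[i] <- emLoglik(fit); conv[i] <- emConverged(fit)
  }
  ok <- !is.na(m1h)
  data.frame(
    bin_id = gr$bin_id[ok],
    chrom = as.character(GenomeInfoDb::seqnames(gr))[ok],
    start = GenomicRanges::start(gr)[ok], end = GenomicRanges::end(gr)[ok],
    m1_hat = m1h[ok], m2_hat = m2h[ok], diff = abs(m1h - m2h)[ok],
    direction = .direction(m1h[ok], m2h[ok]),
    loglik = ll[ok], converged = conv[ok], stringsAsFactors = FALSE)
}

#' Call differentially methylated bins
#'
#' Keeps bins whose between-component methylation difference exceeds the
#' threshold (strictly: a difference exactly equal to the threshold is not
#' called).
#'
#' @param binFits data.frame from \code{\link{fitAllBins}}.
#' @param threshold Difference threshold (default 0.5).
#' @return The called subset of \code{binFits}.
#' @export
callDMBs <- function(binFits, threshold = 0.5) {
  stopifnot(threshold >= 0)
  binFits[binFits$diff > threshold, , drop = FALSE]
}

#' Merge adjacent DMBs into regions
#'
#' Book-ended bins (end of one equals start of the next) on the same
#' chromosome and with the same direction (minor component hyper- vs
#' hypo-methylated) merge into one region; isolated DMBs become single-bin
#' regions. Merging across opposite directions is not allowed: a hyper- and
#' a hypo-methylated pair is two biological events.
#'
#' @param dmbs data.frame of called bins from \code{\link{callDMBs}}.
#' @return \code{GRanges} of DMRs, sorted and disjoint, with metadata
#'   columns \code{n_bins}, \code{mean_diff} and \code{direction}.
#' @export
mergeDMBs <- function(dmbs) {
  if (nrow(dmbs) == 0)
    return(GenomicRanges::GRanges(n_bins = integer(), mean_diff = numeric(),
                                  direction = character()))
  pieces <- lapply(split(dmbs, dmbs$direction), function(d) {
    gr <- .as_granges(d)
    merged <- GenomicRanges::reduce(gr)  # merges book-ended neighbours
    hit <- GenomicRanges::findOverlaps(gr, merged, select = "first")
    merged$n_bins <- as.integer(table(factor(hit, seq_along(merged))))
    merged$mean_diff <- as.numeric(
      tapply(d$diff, factor(hit, seq_along(merged)), mean))
    merged$direction <- rep(unique(d$direction), length(merged))
    merged
  })
  out <- sort(do.call(c, unname(pieces)))
  names(out) <- NULL
  out
}

#' Flag bins with heterogeneous read methylation
#'
#' Computes, per bin, the (population) variance of the per-read methylation
#' fraction \eqn{M_x / l_x} and flags bins exceeding the threshold. Such
#' bins mix more than two read populations (e.g. tumor subclones or
#' allele-specific methylation) and their per-component levels are less
#' trustworthy; flagging is annotation-only.
#'
#' @param binned A \linkS4class{BinnedReads}.
#' @param varThreshold Variance threshold (default 0.1).
#' @return data.frame with \code{bin_id}, \code{read_var} and
#'   \code{flagged}.
#' @export
flagHeterogeneousBins <- function(binned, varThreshold = 0.1) {
  v <- vapply(binned@reads, function(x) {
    if (length(x$M) == 0) return(NA_real_)
    f <- x$M / x$l
    mean((f - mean(f))^2)
  }, numeric(1))
  data.frame(bin_id = binned@bins$bin_id, read_var = v,
             flagged = !is.na(v) & v > varThreshold,
             stringsAsFactors = FALSE)
}
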