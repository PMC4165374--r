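#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importClassesFrom GenomicRanges GRanges
NULL

#' Parameters of the two-component methylation mixture
#'
#' Holds the three free parameters of the per-bin mixture: the methylation
#' levels of the minor and major cell populations and the minor-population
#' fraction. By convention the minor component carries \code{alpha1 <= 0.5}
#' after label normalization; mid-optimization objects may violate this.
#'
#' @slot m1 Methylation level of the minor component, in \eqn{[0, 1]}.
#' @slot m2 Methylation level of the major component, in \eqn{[0, 1]}.
#' @slot alpha1 Minor-component fraction, in \eqn{(0, 1)}; the major
#'   fraction is \code{1 - alpha1}.
#'
#' @examples
#' MixtureParams(m1 = 0.1, m2 = 0.9, alpha1 = 0.3)
#' @name MixtureParams-class
#' @aliases MixtureParams-class
#' @exportClass MixtureParams
setClass("MixtureParams",
  representation(m1 = "numeric", m2 = "numeric", alpha1 = "numeric"))

setValidity("MixtureParams", function(object) {
  msg <- character()
  for (s in c("m1", "m2", "alpha1")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@m1 < 0 || object@m1 > 1) msg <- c(msg, "'m1' must be in [0, 1]")
  if (object@m2 < 0 || object@m2 > 1) msg <- c(msg, "'m2' must be in [0, 1]")
  if (object@alpha1 <= 0 || object@alpha1 >= 1)
    msg <- c(msg, "'alpha1' must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct mixture parameters
#'
#' @param m1,m2 Methylation levels of the minor and major components.
#' @param alpha1 Minor-component fraction in \eqn{(0, 1)}.
#' @return A \linkS4class{MixtureParams} object.
#' @export
MixtureParams <- function(m1, m2, alpha1) {
  new("MixtureParams", m1 = as.numeric(m1), m2 = as.numeric(m2),
      alpha1 = as.numeric(alpha1))
}

setMethod("show", "MixtureParams", function(object) {
  cat(sprintf("MixtureParams: m1 = %.4f, m2 = %.4f, alpha1 = %.4f\n",
              object@m1, object@m2, object@alpha1))
})

#' A converged EM fit for one bin
#'
#' @slot params Converged \linkS4class{MixtureParams}.
#' @slot posteriors Numeric matrix (reads x 2) of membership probabilities
#'   \eqn{Q_x(j)}; rows sum to one.
#' @slot loglik Observed-data log-likelihood at the returned parameters.
#' @slot n_iter Number of EM iterations used.
#' @slot converged Whether the log-likelihood change fell below tolerance.
#' @slot init_label Which initialization produced the returned fit.
#' @slot trace Log-likelihood at each iteration (non-decreasing).
#' @slot unidentifiable Flag for degenerate bins (single read, or all reads
#'   identical) where the mixture split carries no information.
#'
#' @name MixtureFit-class
#' @aliases MixtureFit-class
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(params = "MixtureParams", posteriors = "matrix",
                 loglik = "numeric", n_iter = "integer",
                 converged = "logical", init_label = "character",
                 trace = "numeric", unidentifiable = "logical"))

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit\n")
  cat(sprintf("  m1 = %.4f, m2 = %.4f, alpha1 = %.4f\n",
              object@params@m1, object@params@m2, object@params@alpha1))
  cat(sprintf("  loglik = %.4f after %d iteration(s)%s; init = %s\n",
              object@loglik, object@n_iter,
              if (object@converged) " (converged)" else " (not converged)",
              object@init_label))
  if (object@unidentifiable)
    cat("  flagged unidentifiable (degenerate read set)\n")
})

#' Reads binned on a genome tiling
#'
#' Container produced by \code{\link{assignReadsToBins}}: a tiling of the
#' genome into fixed-width bins plus, per bin, the clipped binary CpG
#' methylation vectors of every read overlapping it.
#'
#' @slot bins A \link[GenomicRanges]{GRanges} of bins, with metadata columns
#'   \code{bin_id}, \code{short} (terminal bin shorter than the tile width),
#'   \code{n_cpg} and \code{coverage} (read count).
#' @slot reads A list parallel to \code{bins}; each element is a list with
#'   components \code{read_id}, \code{M} (methylated-call count per read),
#'   \code{l} (call count per read), \code{calls} (list of 0/1 integer
#'   vectors) and \code{pos} (list of 1-based CpG C positions).
#' @slot qc Named list of quality-control counters.
#'
#' @name BinnedReads-class
#' @aliases BinnedReads-class
#' @exportClass BinnedReads
setClass("BinnedReads",
  representation(bins = "GRanges", reads = "list", qc = "list"))

setValidity("BinnedReads", function(object) {
  if (length(object@reads) != length(object@bins))
    return("'reads' must be parallel to 'bins'")
  TRUE
})

setMethod("show", "BinnedReads", function(object) {
  cov <- object@bins$coverage
  cat(sprintf("BinnedReads: %d bins on %d sequence(s)\n",
              length(object@bins),
              length(GenomeInfoDb::seqlevels(object@bins))))
  cat(sprintf("  reads per bin: median %s, max %s; %d bin(s) non-empty\n",
              stats::median(cov), max(cov, 0), sum(cov > 0)))
})

#' Genome annotation used by the purity pipeline
#'
#' @slot cpgIslands \link[GenomicRanges]{GRanges} of CpG islands.
#' @slot cnaRegions \link[GenomicRanges]{GRanges} of recurrent copy-number
#'   aberration regions to exclude (with flank) from informative-bin search.
#' @slot chromSizes Named integer vector of chromosome lengths.
#'
#' @name GenomeAnnotation-class
#' @aliases GenomeAnnotation-class
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(cpgIslands = "GRanges", cnaRegions = "GRanges",
                 chromSizes = "integer"))

#' Construct a genome annotation
#'
#' @param cpgIslands,cnaRegions \code{GRanges} (either may be empty).
#' @param chromSizes Named integer vector of chromosome lengths.
#' @return A \linkS4class{GenomeAnnotation} object.
#' @export
GenomeAnnotation <- function(cpgIslands = GRanges(),
                             cnaRegions = GRanges(),
                             chromSizes = integer()) {
  new("GenomeAnnotation", cpgIslands = cpgIslands, cnaRegions = cnaRegions,
      chromSizes = as.integer(setNames(chromSizes, names(chromSizes))))
}

#' Voted sample purity estimate
#'
#' @slot alpha1 The voted minor-component fraction (mode of the per-bin
#'   votes' kernel density), in \eqn{(0, 0.5]}.
#' @slot nInformative Number of informative bins that voted.
#' @slot votes Per-bin mean bootstrap \eqn{\alpha_1} values.
#' @slot bandwidth Gaussian kernel bandwidth used for the density mode.
#' @slot density data.frame with the density grid (\code{alpha1},
#'   \code{density}).
#' @slot informative data.frame describing the informative bins
#'   (coordinates, sd of m1, mean alpha1).
#' @slot qc Named list of per-stage counters (bins in, CNA-filtered, ...).
#'
#' @name PurityEstimate-class
#' @aliases PurityEstimate-class
#' @exportClass PurityEstimate
setClass("PurityEstimate",
  representation(alpha1 = "numeric", nInformative = "integer",
                 votes = "numeric", bandwidth = "numeric",
                 density = "data.frame", informative = "data.frame",
                 qc = "list"))

setMethod("show", "PurityEstimate", function(object) {
  cat("PurityEstimate\n")
  cat(sprintf("  minor-component fraction (alpha1): %.3f\n", object@alpha1))
  cat(sprintf("  voted by %d informative bins (KDE bandwidth %.3f)\n",
              object@nInformative, object@bandwidth))
})
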