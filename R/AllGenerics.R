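#' Accessors for methDeconv result objects
#'
#' Small accessor generics so downstream code never reaches into slots:
#' \code{alpha1()}, \code{m1()}, \code{m2()} read mixture parameters from a
#' \linkS4class{MixtureParams}, \linkS4class{MixtureFit} or
#' \linkS4class{PurityEstimate}; \code{emLoglik()} and \code{emConverged()}
#' read fit diagnostics; \code{binRanges()} and \code{binReads()} read the
#' tiling and per-bin read sets of a \linkS4class{BinnedReads};
#' \code{purityVotes()} and \code{nInformative()} read voting details from a
#' \linkS4class{PurityEstimate}.
#'
#' @param x The object.
#' @param i For \code{binReads}, a bin index or \code{bin_id} string.
#' @return The corresponding component (numeric scalar, \code{GRanges},
#'   list, or data.frame).
#' @name accessors
#' @aliases alpha1 m1 m2 emLoglik emConverged binRanges binReads
#'   purityVotes nInformative
#' @examples
#' p <- MixtureParams(0.1, 0.9, 0.3)
#' alpha1(p)
NULL

#' @rdname accessors
#' @export
setGeneric("alpha1", function(x) standardGeneric("alpha1"))
#' @rdname accessors
#' @export
setGeneric("m1", function(x) standardGeneric("m1"))
#' @rdname accessors
#' @export
setGeneric("m2", function(x) standardGeneric("m2"))
#' @rdname accessors
#' @export
setGeneric("emLoglik", function(x) standardGeneric("emLoglik"))
#' @rdname accessors
#' @export
setGeneric("emConverged", function(x) standardGeneric("emConverged"))
#' @rdname accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))
#' @rdname accessors
#' @export
setGeneric("binReads", function(x, i) standardGeneric("binReads"))
#' @rdname accessors
#' @export
setGeneric("purityVotes", function(x) standardGeneric("purityVotes"))
#' @rdname accessors
#' @export
setGeneric("nInformative", function(x) standardGeneric("nInformative"))

#' @rdname accessors
setMethod("alpha1", "MixtureParams", function(x) x@alpha1)
#' @rdname accessors
setMethod("m1", "MixtureParams", function(x) x@m1)
#' @rdname accessors
setMethod("m2", "MixtureParams", function(x) x@m2)
#' @rdname accessors
setMethod("alpha1", "MixtureFit", function(x) x@params@alpha1)
#' @rdname accessors
setMethod("m1", "MixtureFit", function(x) x@params@m1)
#' @rdname accessors
setMethod("m2", "MixtureFit", function(x) x@params@m2)
#' @rdname accessors
setMethod("emLoglik", "MixtureFit", function(x) x@loglik)
#' @rdname accessors
setMethod("emConverged", "MixtureFit", function(x) x@converged)
#' @rdname accessors
setMethod("alpha1", "PurityEstimate", function(x) x@alpha1)
#' @rdname accessors
setMethod("purityVotes", "PurityEstimate", function(x) x@votes)
#' @rdname accessors
setMethod("nInformative", "PurityEstimate", function(x) x@nInformative)
#' @rdname accessors
setMethod("binRanges", "BinnedReads", function(x) x@bins)
#' @rdname accessors
setMethod("binReads", "BinnedReads", function(x, i) {
  if (missing(i)) return(x@reads)
  if (is.character(i)) i <- match(i, x@bins$bin_id)
  x@reads[[i]]
})
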