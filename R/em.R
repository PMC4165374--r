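## Two-component EM over a bin's read set.
##
## A read x with M methylated and U unmethylated CpG calls has component
## density p_{x,j} = m_j^M (1-m_j)^U; the bin likelihood is
## l(X) = sum_x log(alpha1 p_{x,1} + alpha2 p_{x,2}). The E-step computes
## posteriors Q_x(j) and the M-step the closed-form updates
## m_j = sum Q_x(j) M_x / sum Q_x(j) l_x, alpha1 = mean Q_x(1).

.EM_EPS <- 1e-6  # clamp on m inside log densities

.clamp_m <- function(m) pmin(1 - .EM_EPS, pmax(.EM_EPS, m))

## Normalize the many accepted read-set representations to list(M, l):
## a list of 0/1 call vectors, a matrix/data.frame with columns M and l,
## a list with components M and l, or a bin record from a BinnedReads.
.as_counts <- function(X) {
  if (is.matrix(X) || is.data.frame(X)) {
    stopifnot(all(c("M", "l") %in% colnames(X)))
    return(list(M = as.numeric(X[, "M"]), l = as.numeric(X[, "l"])))
  }
  if (is.list(X) && !is.null(X$M) && !is.null(X$l))
    return(list(M = as.numeric(X$M), l = as.numeric(X$l)))
  if (is.list(X)) {  # list of binary call vectors
    l <- lengths(X)
    M <- vapply(X, sum, numeric(1))
    return(list(M = as.numeric(M), l = as.numeric(l)))
  }
  stop("cannot interpret 'X' as a read set")
}

.params_vec <- function(params) {
  if (is(params, "MixtureParams"))
    c(m1 = params@m1, m2 = params@m2, alpha1 = params@alpha1)
  else c(m1 = params[["m1"]], m2 = params[["m2"]], alpha1 = params[["alpha1"]])
}

#' Log-probability of one read under a single component
#'
#' Computes \eqn{\log p_{x,j} = M_x \log m + U_x \log(1 - m)} for a read's
#' binary call vector under methylation level \code{m}. The level is clamped
#' to \eqn{[10^{-6}, 1 - 10^{-6}]} inside the logs so that calls impossible
#' under \code{m} in \{0, 1\} stay finite.
#'
#' @param calls Integer vector of 0/1 CpG methylation calls (or a list with
#'   components \code{M} and \code{l}).
#' @param m Methylation level in \eqn{[0, 1]}.
#' @return The log-probability (a single number, possibly very negative).
#' @examples
#' componentLogLik(c(1, 1), 1)            # 0
#' componentLogLik(c(1, 0), 0.5)          # log 0.25
#' @export
componentLogLik <- function(calls, m) {
  stopifnot(m >= 0, m <= 1)
  cc <- .as_counts(if (is.list(calls)) calls else list(calls))
  mc <- .clamp_m(m)
  sum(cc$M * log(mc) + (cc$l - cc$M) * log1p(-mc))
}

#' Mixture log-likelihood of a read set
#'
#' \eqn{l(X) = \sum_x \log(\alpha_1 p_{x,1} + \alpha_2 p_{x,2})}, evaluated
#' with log-sum-exp.
#'
#' @param X Read set: a list of 0/1 call vectors, a matrix with columns
#'   \code{M} and \code{l}, or a list with components \code{M}, \code{l}.
#' @param params A \linkS4class{MixtureParams} (or named vector with
#'   \code{m1}, \code{m2}, \code{alpha1}).
#' @return Log-likelihood (finite for valid inputs).
#' @export
mixtureLogLik <- function(X, params) {
  cc <- .as_counts(X)
  stopifnot(length(cc$M) > 0)
  p <- .params_vec(params)
  cpp_loglik(cc$M, cc$l, p["m1"], p["m2"], p["alpha1"])
}

#' E-step: posterior component memberships
#'
#' \eqn{Q_x(j) = \alpha_j p_{x,j} / (\alpha_1 p_{x,1} + \alpha_2 p_{x,2})},
#' computed via log-sum-exp.
#'
#' @inheritParams mixtureLogLik
#' @return Numeric matrix (reads x 2) with columns \code{Q1}, \code{Q2};
#'   rows sum to one.
#' @export
eStep <- function(X, params) {
  cc <- .as_counts(X)
  p <- .params_vec(params)
  m1c <- .clamp_m(p["m1"]); m2c <- .clamp_m(p["m2"])
  U <- cc$l - cc$M
  lp1 <- log(p["alpha1"]) + cc$M * log(m1c) + U * log1p(-m1c)
  lp2 <- log1p(-p["alpha1"]) + cc$M * log(m2c) + U * log1p(-m2c)
  mx <- pmax(lp1, lp2)
  lse <- mx + log(exp(lp1 - mx) + exp(lp2 - mx))
  out <- cbind(Q1 = exp(lp1 - lse), Q2 = exp(lp2 - lse))
  rownames(out) <- NULL
  out
}

#' M-step: closed-form parameter updates
#'
#' \eqn{m_j = \sum_x Q_x(j) M_x / \sum_x Q_x(j) l_x} and
#' \eqn{\alpha_1 = \sum_x Q_x(1) / |X|}. A component whose weighted call
#' total is zero keeps its previous level (supplied via \code{prev}).
#'
#' @inheritParams mixtureLogLik
#' @param posteriors Matrix from \code{\link{eStep}}.
#' @param prev Optional previous \linkS4class{MixtureParams}, used when a
#'   denominator vanishes.
#' @return A \linkS4class{MixtureParams}. No label normalization is applied
#'   here; \code{alpha1} may exceed 0.5 mid-run.
#' @export
mStep <- function(X, posteriors, prev = NULL) {
  cc <- .as_counts(X)
  q1 <- posteriors[, 1]; q2 <- posteriors[, 2]
  sl1 <- sum(q1 * cc$l); sl2 <- sum(q2 * cc$l)
  pv <- if (is.null(prev)) c(m1 = 0.5, m2 = 0.5) else .params_vec(prev)
  m1 <- if (sl1 > 0) sum(q1 * cc$M) / sl1 else unname(pv["m1"])
  m2 <- if (sl2 > 0) sum(q2 * cc$M) / sl2 else unname(pv["m2"])
  a1 <- min(1 - 1e-9, max(1e-9, mean(q1)))
  MixtureParams(m1 = m1, m2 = m2, alpha1 = a1)
}

.is_degenerate <- function(cc) {
  length(cc$M) < 2 ||
    length(unique(paste(cc$M, cc$l))) < 2
}

.mk_fit <- function(cc, r, init_label) {
  params <- MixtureParams(r$m1, r$m2, min(1 - 1e-9, max(1e-9, r$alpha1)))
  post <- eStep(cc, params)
  new("MixtureFit", params = params, posteriors = post,
      loglik = r$loglik, n_iter = as.integer(r$n_iter),
      converged = r$converged, init_label = init_label,
      trace = as.numeric(r$trace), unidentifiable = .is_degenerate(cc))
}

#' Run the EM algorithm on one bin
#'
#' Iterates E- and M-steps until the log-likelihood change falls below
#' \code{tol} or \code{maxIter} is reached. With \code{fixAlpha} supplied,
#' \eqn{\alpha_1} is held fixed and only the two methylation levels are
#' updated (the fit keeps its initialization's component identity). In the
#' free-\eqn{\alpha} case labels are normalized at convergence so that
#' \code{alpha1 <= 0.5}; if \code{init} is omitted the fit is started from
#' the two deterministic starts \code{(m1, m2) = (0.2, 0.8)} and
#' \code{(0.8, 0.2)} and the higher-likelihood convergence point is kept.
#'
#' @inheritParams mixtureLogLik
#' @param init Optional \linkS4class{MixtureParams} initialization.
#' @param fixAlpha Optional fixed minor fraction in \eqn{(0, 0.5]}.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param maxIter Iteration cap.
#' @return A \linkS4class{MixtureFit}.
#' @examples
#' X <- c(rep(list(c(1, 1, 1)), 7), rep(list(c(0, 0, 0)), 3))
#' fit <- runEM(X)
#' alpha1(fit)   # ~0.3
#' @export
runEM <- function(X, init = NULL, fixAlpha = NULL, tol = 1e-6,
                  maxIter = 500L) {
  cc <- .as_counts(X)
  stopifnot(length(cc$M) > 0)
  if (!is.null(fixAlpha)) {
    stopifnot(fixAlpha > 0, fixAlpha <= 0.5)
    p <- if (is.null(init)) c(m1 = 0.2, m2 = 0.8) else .params_vec(init)
    r <- cpp_em_fit(cc$M, cc$l, p[["m1"]], p[["m2"]], fixAlpha,
                    TRUE, tol, as.integer(maxIter), FALSE)
    r$alpha1 <- fixAlpha
    fit <- .mk_fit(cc, r, sprintf("fixed-alpha m1=%.2f", p[["m1"]]))
  } else if (!is.null(init)) {
    p <- .params_vec(init)
    r <- cpp_em_fit(cc$M, cc$l, p[["m1"]], p[["m2"]], p[["alpha1"]],
                    FALSE, tol, as.integer(maxIter), TRUE)
    fit <- .mk_fit(cc, r, "user")
  } else {
    r <- cpp_em_fit_free_dual(cc$M, cc$l, tol, as.integer(maxIter))
    fit <- .mk_fit(cc, r, "dual-start")
  }
  if (!is.finite(fit@loglik))
    stop("non-finite likelihood while fitting a bin")
  fit
}

#' Dual-initialization fixed-alpha fit for one bin
#'
#' The per-bin likelihood at fixed \eqn{\alpha_1} can hold two local maxima
#' (minor component hyper- vs hypo-methylated). The fit is started from
#' \code{(m1, m2) = (0.2, 0.8)} and \code{(0.8, 0.2)} and the convergence
#' point with the higher likelihood is returned; exact ties resolve to the
#' fit with \code{m1 <= m2}.
#'
#' @inheritParams runEM
#' @param fixAlpha Fixed minor fraction in \eqn{(0, 0.5]}.
#' @return A \linkS4class{MixtureFit} whose \code{init_label} records the
#'   winning start.
#' @export
fitBinDualInit <- function(X, fixAlpha, tol = 1e-6, maxIter = 500L) {
  stopifnot(fixAlpha > 0, fixAlpha <= 0.5)
  a <- runEM(X, init = MixtureParams(0.2, 0.8, fixAlpha),
             fixAlpha = fixAlpha, tol = tol, maxIter = maxIter)
  b <- runEM(X, init = MixtureParams(0.8, 0.2, fixAlpha),
             fixAlpha = fixAlpha, tol = tol, maxIter = maxIter)
  if (a@loglik > b@loglik) return(a)
  if (b@loglik > a@loglik) return(b)
  if (m1(a) <= m2(a)) a else b
}
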