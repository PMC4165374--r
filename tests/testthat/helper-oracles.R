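# Independent oracles and small-instance generators for the EM tests.

# Random read-set instance: n reads with up to l_max CpG calls each,
# mixed from two random levels at a random fraction.
rand_instance <- function(n_max = 30, l_max = 8, n_min = 2) {
  n <- sample(n_min:n_max, 1)
  l <- sample(1:l_max, n, replace = TRUE)
  mA <- runif(1)
  mB <- runif(1)
  a <- runif(1, 0.1, 0.9)
  z <- rbinom(n, 1, a)
  m <- ifelse(z == 1, mA, mB)
  M <- rbinom(n, l, m)
  list(M = as.numeric(M), l = as.numeric(l))
}

rand_params <- function() {
  MixtureParams(m1 = runif(1, 0.05, 0.95), m2 = runif(1, 0.05, 0.95),
                alpha1 = runif(1, 0.05, 0.95))
}

# Clamped per-read component log-density, written independently of the
# package internals.
oracle_comp_lp <- function(M, U, m) {
  mc <- min(1 - 1e-6, max(1e-6, m))
  M * log(mc) + U * log1p(-mc)
}

# Mixture log-likelihood by brute-force enumeration over all 2^n component
# assignment vectors: log sum_z prod_x alpha_{z_x} p_{x, z_x}.
oracle_enum_loglik <- function(X, params) {
  n <- length(X$M)
  stopifnot(n <= 12)
  U <- X$l - X$M
  lp1 <- log(alpha1(params)) + oracle_comp_lp(X$M, U, m1(params))
  lp2 <- log1p(-alpha1(params)) + oracle_comp_lp(X$M, U, m2(params))
  grid <- as.matrix(expand.grid(rep(list(c(1, 2)), n)))
  lps <- apply(grid, 1, function(z) sum(ifelse(z == 1, lp1, lp2)))
  mx <- max(lps)
  mx + log(sum(exp(lps - mx)))
}

# Jensen lower bound J(X; Q) at posteriors Q and parameters theta.
oracle_jbound <- function(X, Q, m1v, m2v, a1v) {
  U <- X$l - X$M
  lp1 <- oracle_comp_lp(X$M, U, m1v)
  lp2 <- oracle_comp_lp(X$M, U, m2v)
  q1 <- Q[, 1]; q2 <- Q[, 2]
  lg <- function(x) ifelse(x > 0, log(x), 0)  # 0 log 0 = 0 convention
  sum(q1 * (log(a1v) + lp1 - lg(q1)) + q2 * (log1p(-a1v) + lp2 - lg(q2)))
}

# Numeric maximization of the Jensen bound over (m1, m2, alpha1); the
# analytic M-step must agree with this. The bound is additively separable
# and concave in each coordinate; small finite-difference steps and a
# tight stopping rule are needed to localize the optimum in nearly-flat
# directions (a component with near-zero posterior weight).
oracle_numeric_mstep <- function(X, Q) {
  U <- X$l - X$M
  f <- function(p) -oracle_jbound(X, Q, p[1], p[2], p[3])
  # exact gradient of -J (finite differences stray outside the box and
  # stall in nearly-flat directions)
  g <- function(p) {
    q1 <- Q[, 1]; q2 <- Q[, 2]
    -c(sum(q1 * X$M) / p[1] - sum(q1 * U) / (1 - p[1]),
       sum(q2 * X$M) / p[2] - sum(q2 * U) / (1 - p[2]),
       sum(q1) / p[3] - sum(q2) / (1 - p[3]))
  }
  fit <- optim(c(0.5, 0.5, 0.5), f, g, method = "L-BFGS-B",
               lower = rep(1e-9, 3), upper = rep(1 - 1e-9, 3),
               control = list(factr = 10, pgtol = 0, maxit = 5000))
  fit$par
}

# Fully concordant read set: n1 unmethylated + n2 methylated reads of l CpGs.
dichotomous_bin <- function(n_unmeth, n_meth, l = 5) {
  list(M = c(rep(0, n_unmeth), rep(l, n_meth)),
       l = rep(l, n_unmeth + n_meth))
}

# Small simulated sample routed through the standard binning path.
sim_binned <- function(..., seed = 1) {
  sim <- simulateMixture(simConfig(..., seed = seed))
  bins <- tileBins(sim$genome$chromSizes, sim$genome$config$binSize)
  list(sim = sim,
       binned = assignReadsToBins(sim$reads, bins))
}

# Build a read DataFrame like loadReadCallTable()'s output, from 1-based
# CpG positions.
mk_reads <- function(pos, calls, chrom = "chr1",
                     read_id = sprintf("r%03d", seq_along(pos)),
                     strand = rep("+", length(pos)),
                     start = vapply(pos, min, numeric(1)),
                     end = vapply(pos, max, numeric(1)) + 1) {
  df <- S4Vectors::DataFrame(
    read_id = read_id, chrom = rep(chrom, length(pos)),
    start = as.integer(start), end = as.integer(end), strand = strand,
    pos = IRanges::IntegerList(pos),
    calls = IRanges::IntegerList(calls))
  df
}

# Write a SAM file from parallel vectors; qual omitted.
write_sam <- function(path, chrom, chromlen, qname, flag, pos, seq) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chromlen))
  lines <- paste(qname, flag, chrom, pos, 60L,
                 paste0(nchar(seq), "M"), "*", 0L, 0L, seq, "*",
                 sep = "\t")
  writeLines(c(hdr, lines), path)
  path
}
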