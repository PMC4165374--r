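mk_summaries <- function(sd_m1, start = seq_along(sd_m1) * 300 + 1,
                         mean_alpha1 = 0.3, mean_sep = 1) {
  n <- length(sd_m1)
  data.frame(bin_id = sprintf("b%04d", seq_len(n)), chrom = "chr1",
             start = start, end = start + 299, coverage = 70, n_cpg = 20,
             sd_m1 = sd_m1, sd_m2 = 0.01, sd_alpha1 = 0.02,
             mean_alpha1 = rep_len(mean_alpha1, n),
             mean_sep = rep_len(mean_sep, n), failed = FALSE,
             stringsAsFactors = FALSE)
}

test_that("bootstrap summarizes parameter stability per bin", {
  # well-separated unbalanced bin: minor label is stable across
  # resamples, components pinned near 0 and 1
  X <- dichotomous_bin(30, 70, l = 5)
  set.seed(1)
  b <- bootstrapBin(X)
  expect_equal(b$n_boot, 50L)
  expect_false(b$failed)
  expect_lt(b$sd_m1, 0.1)
  expect_gt(b$mean_sep, 0.9)
  expect_equal(nrow(b$params), 50)
  expect_true(all(b$params[, "alpha1"] <= 0.5))

  # balanced 50/50 bin: which component is minor flips between
  # resamples, so the minor-level estimate fluctuates between 0 and 1
  X <- dichotomous_bin(50, 50, l = 5)
  set.seed(1)
  b <- bootstrapBin(X)
  expect_gt(b$sd_m1, 0.3)

  # uniform bin: components collapse, no mixture signal
  X <- list(M = rep(c(5, 4), 25), l = rep(5, 50))
  set.seed(2)
  b <- bootstrapBin(X)
  expect_lt(b$mean_sep, 0.2)

  # determinism under an identical seed
  X <- dichotomous_bin(20, 50, l = 6)
  set.seed(99); b1 <- bootstrapBin(X)
  set.seed(99); b2 <- bootstrapBin(X)
  expect_identical(b1, b2)
})

test_that("CNA regions plus flanks remove overlapping bins", {
  sm <- mk_summaries(c(0.01, 0.01), start = c(1, 5001))
  # 0-based CNA [1200,1500) with 1000 bp flank reaches into bin [0,300)
  cna <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1201, 1500))
  out <- filterCNA(sm, cna, flank = 1000)
  expect_equal(out$start, 5001)
  # CNA [1400,1500): flank stops at 400, bin kept
  cna <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1401, 1500))
  expect_equal(nrow(filterCNA(sm, cna, flank = 1000)), 2)
  # empty CNA set is the identity
  expect_identical(filterCNA(sm, GenomicRanges::GRanges()), sm)
})

test_that("at most one bin per CpG island is kept, by smallest sd(m1)", {
  sm <- mk_summaries(c(0.02, 0.05, 0.03), start = c(1, 301, 10001))
  isl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 10100),
                                                         c(500, 10200)))
  out <- dedupeByIsland(sm, isl)
  expect_equal(out$start, c(1, 10001))  # sd 0.02 beats 0.05; 2nd island kept
  # bins in no island pass through
  sm <- mk_summaries(c(0.05, 0.02), start = c(20001, 20301))
  expect_equal(nrow(dedupeByIsland(sm, isl)), 2)
})

test_that("informative-bin selection ranks by sd(m1) and enforces a minimum", {
  set.seed(3)
  sm <- mk_summaries(runif(700, 0.01, 0.2))
  sel <- selectInformative(sm, sdThreshold = 0.1, topN = 500,
                           minInformative = 100)
  expect_lte(nrow(sel), 500)
  expect_true(all(sel$sd_m1 < 0.1))
  expect_false(is.unsorted(sel$sd_m1))

  # 600 eligible bins -> exactly the top 500
  sm <- mk_summaries(seq(0.001, 0.099, length.out = 600))
  expect_equal(nrow(selectInformative(sm, minInformative = 500)), 500)
  # exactly 500 eligible -> all returned
  sm <- mk_summaries(seq(0.001, 0.099, length.out = 500))
  expect_equal(nrow(selectInformative(sm, minInformative = 500)), 500)
  # 66 eligible -> the pure-sample error
  sm <- mk_summaries(c(rep(0.05, 66), rep(0.5, 500)))
  err <- tryCatch(selectInformative(sm, minInformative = 500),
                  insufficientInformativeBins = function(e) e)
  expect_s3_class(err, "insufficientInformativeBins")
  expect_match(conditionMessage(err), "66 found")
  expect_match(conditionMessage(err), "less than 5%")
  # collapsed or near-zero-alpha bins are not informative
  sm <- mk_summaries(rep(0.01, 100), mean_sep = 0.05)
  expect_error(selectInformative(sm, minInformative = 50),
               class = "insufficientInformativeBins")
  sm <- mk_summaries(rep(0.01, 100), mean_alpha1 = 0.01)
  expect_error(selectInformative(sm, minInformative = 50),
               class = "insufficientInformativeBins")
})

test_that("alpha voting takes the kernel-density mode on (0, 0.5]", {
  est <- voteAlpha(rep(0.30, 200))
  expect_equal(alpha1(est), 0.30)
  expect_equal(nInformative(est), 200L)

  set.seed(4)
  v <- pmin(0.5, pmax(0.001, rnorm(500, 0.3, 0.03)))
  expect_gte(alpha1(voteAlpha(v)), 0.28)
  expect_lte(alpha1(voteAlpha(v)), 0.32)

  v <- c(rep(0.2, 400), rep(0.4, 100))
  expect_equal(alpha1(voteAlpha(v)), 0.2, tolerance = 0.01)
  # the estimate never leaves (0, 0.5]
  expect_lte(alpha1(voteAlpha(rep(0.49, 50))), 0.5)
})

test_that("purity estimation is deterministic and bounded by 0.5", {
  sb <- sim_binned(nBins = 150, alpha1 = 0.3, seed = 21)
  cfg <- deconvConfig(minInformative = 10, seed = 21)
  e1 <- estimatePurity(sb$binned, config = cfg)
  e2 <- estimatePurity(sb$binned, config = cfg)
  expect_identical(alpha1(e1), alpha1(e2))
  expect_identical(purityVotes(e1), purityVotes(e2))
  # at this desk scale only ~30 bins vote, so the mode is coarse
  expect_lt(abs(alpha1(e1) - 0.3), 0.05)
  expect_lte(alpha1(e1), 0.5)
  expect_gt(nInformative(e1), 10)

  # equal mixing: the minor-fraction estimate can never exceed one half;
  # balanced bins are often label-unstable, so the sample may instead be
  # reported as lacking informative bins
  sb <- sim_binned(nBins = 150, alpha1 = 0.5, seed = 22)
  e <- tryCatch(
    estimatePurity(sb$binned,
                   config = deconvConfig(minInformative = 10, seed = 22)),
    insufficientInformativeBins = function(e) e)
  if (is(e, "PurityEstimate")) expect_lte(alpha1(e), 0.5)
  else expect_s3_class(e, "insufficientInformativeBins")
})

test_that("a pure sample raises the insufficient-informative-bins error", {
  sb <- sim_binned(nBins = 120, alpha1 = 0, seed = 23)
  expect_error(
    estimatePurity(sb$binned,
                   config = deconvConfig(minInformative = 20, seed = 23)),
    class = "insufficientInformativeBins")
})
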