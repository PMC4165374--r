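test_that("component log-likelihood matches closed forms", {
  expect_equal(componentLogLik(c(1, 1), 1), 0, tolerance = 1e-5)
  expect_equal(componentLogLik(c(1, 0), 0.5), log(0.25))
  expect_equal(componentLogLik(c(1, 0, 1), 0.8), log(0.8^2 * 0.2))
  # certain-miss events are clamped, not -Inf
  expect_true(is.finite(componentLogLik(c(0), 1)))
})

test_that("mixture log-likelihood degenerates and enumerates correctly", {
  X <- list(M = c(2, 0, 1), l = c(3, 2, 1))
  # m1 = m2: mixture collapses to one component, independent of alpha
  for (a in c(0.1, 0.4)) {
    expect_equal(mixtureLogLik(X, MixtureParams(0.3, 0.3, a)),
                 sum(oracle_comp_lp(X$M, X$l - X$M, 0.3)))
  }
  # single decisive read
  expect_equal(mixtureLogLik(list(M = 1, l = 1), MixtureParams(1, 0, 0.3)),
               log(0.3), tolerance = 1e-5)
  # 4-read fixture against brute-force assignment enumeration
  X4 <- list(M = c(3, 0, 2, 1), l = c(3, 3, 4, 2))
  p <- MixtureParams(0.15, 0.85, 0.35)
  expect_equal(mixtureLogLik(X4, p), oracle_enum_loglik(X4, p),
               tolerance = 1e-12)
})

test_that("E-step posteriors are normalized and match the direct ratio", {
  X <- list(M = c(3, 0), l = c(3, 3))
  # m1 = m2: every read is uninformative, Q1 = alpha1
  Q <- eStep(X, MixtureParams(0.5, 0.5, 0.27))
  expect_equal(unname(Q[, 1]), rep(0.27, 2))
  # decisive read
  Q <- eStep(list(M = 3, l = 3), MixtureParams(1e-6, 1 - 1e-6, 0.3))
  expect_gt(Q[1, 2], 1 - 1e-6)
  # random instances vs the direct ratio formula
  set.seed(42)
  for (i in 1:50) {
    X <- rand_instance(10, 6)
    p <- rand_params()
    Q <- eStep(X, p)
    expect_equal(unname(rowSums(Q)), rep(1, length(X$M)), tolerance = 1e-9)
    U <- X$l - X$M
    a1 <- alpha1(p)
    w1 <- a1 * exp(oracle_comp_lp(X$M, U, m1(p)))
    w2 <- (1 - a1) * exp(oracle_comp_lp(X$M, U, m2(p)))
    expect_equal(unname(Q[, 1]), w1 / (w1 + w2), tolerance = 1e-12)
  }
})

test_that("M-step updates match their closed form and the Jensen bound", {
  # all reads assigned to component 1, all methylated
  X <- list(M = c(2, 3), l = c(2, 3))
  p <- mStep(X, cbind(c(1, 1), c(0, 0)), prev = MixtureParams(0.5, 0.5, 0.5))
  expect_equal(m1(p), 1)
  expect_equal(alpha1(p), 1 - 1e-9)
  # hard split of two opposite reads
  p <- mStep(list(M = c(1, 0), l = c(1, 1)), cbind(c(1, 0), c(0, 1)))
  expect_equal(c(m1(p), m2(p), alpha1(p)), c(1, 0, 0.5))
  # analytic M-step is the maximizer of J(X; Q) on random instances
  set.seed(7)
  for (i in 1:25) {
    X <- rand_instance(20, 6)
    Q <- eStep(X, rand_params())
    p <- mStep(X, Q)
    opt <- oracle_numeric_mstep(X, Q)
    expect_equal(c(m1(p), m2(p), alpha1(p)), opt, tolerance = 1e-4)
  }
})

test_that("free-alpha EM recovers a separable mixture and labels the minor component", {
  X <- dichotomous_bin(n_unmeth = 3, n_meth = 7, l = 3)
  fit <- runEM(X)
  expect_equal(alpha1(fit), 0.3, tolerance = 1e-3)
  expect_equal(sort(c(m1(fit), m2(fit))), c(0, 1), tolerance = 1e-3)
  expect_lte(alpha1(fit), 0.5)
  expect_true(emConverged(fit))
  # likelihood-grid cross-check: the converged fit beats a coarse grid
  grid <- expand.grid(m1 = seq(0.05, 0.95, 0.15),
                      m2 = seq(0.05, 0.95, 0.15),
                      a1 = seq(0.05, 0.5, 0.05))
  gl <- max(apply(grid, 1, function(g)
    mixtureLogLik(X, MixtureParams(g[1], g[2], g[3]))))
  expect_gte(emLoglik(fit), gl - 1e-8)
})

test_that("fixed-alpha EM estimates the methylation levels only", {
  X <- dichotomous_bin(3, 7, l = 3)
  fit <- runEM(X, init = MixtureParams(0.2, 0.8, 0.3), fixAlpha = 0.3)
  expect_equal(alpha1(fit), 0.3)
  expect_equal(m1(fit), 0, tolerance = 1e-3)
  expect_equal(m2(fit), 1, tolerance = 1e-3)
})

test_that("identical reads give an unidentifiable flat fit", {
  X <- list(M = rep(3, 8), l = rep(3, 8))
  fit <- runEM(X)
  expect_true(fit@unidentifiable)
  expect_equal(m1(fit), m2(fit), tolerance = 1e-6)
  # loglik equals the single-component value
  expect_equal(emLoglik(fit),
               sum(oracle_comp_lp(X$M, X$l - X$M, 1)), tolerance = 1e-6)
})

test_that("dual-init selection returns the higher-likelihood optimum", {
  X <- dichotomous_bin(4, 6, l = 4)
  best <- fitBinDualInit(X, fixAlpha = 0.4)
  a <- runEM(X, init = MixtureParams(0.2, 0.8, 0.4), fixAlpha = 0.4)
  b <- runEM(X, init = MixtureParams(0.8, 0.2, 0.4), fixAlpha = 0.4)
  expect_gte(emLoglik(best), emLoglik(a))
  expect_gte(emLoglik(best), emLoglik(b))
  # unimodal bin: both inits agree
  X1 <- list(M = c(4, 3, 4, 4, 3), l = rep(4, 5))
  a <- runEM(X1, init = MixtureParams(0.2, 0.8, 0.3), fixAlpha = 0.3,
             tol = 1e-12, maxIter = 5000)
  b <- runEM(X1, init = MixtureParams(0.8, 0.2, 0.3), fixAlpha = 0.3,
             tol = 1e-12, maxIter = 5000)
  expect_equal(sort(c(m1(a), m2(a))), sort(c(m1(b), m2(b))),
               tolerance = 1e-4)
})

test_that("log-likelihood trace is non-decreasing and label-swap symmetric", {
  set.seed(11)
  for (i in 1:200) {
    X <- rand_instance(15, 6)
    init <- rand_params()
    fit <- runEM(X, init = init)
    expect_true(all(diff(fit@trace) >= -1e-8))
    # label-swap symmetry of the likelihood itself
    p <- rand_params()
    swapped <- MixtureParams(m2(p), m1(p), 1 - alpha1(p))
    expect_equal(mixtureLogLik(X, p), mixtureLogLik(X, swapped),
                 tolerance = 1e-12)
  }
})

test_that("a converged fit is a fixed point of E followed by M", {
  set.seed(13)
  for (i in 1:20) {
    X <- rand_instance(20, 6, n_min = 5)
    fit <- runEM(X, tol = 1e-10, maxIter = 2000)
    p0 <- fit@params
    p1 <- mStep(X, eStep(X, p0), prev = p0)
    expect_equal(c(m1(p1), m2(p1), alpha1(p1)),
                 c(m1(p0), m2(p0), alpha1(p0)), tolerance = 1e-4)
  }
})
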