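# Scanning, stepwise conditional detection, joint fitting, closed-form
# bias, power and sample-size machinery.

test_that("univariate scan is calibrated under the null", {
  set.seed(1)
  X <- matrix(rbinom(2000 * 1000, 2, 0.3), nrow = 2000)
  y <- rnorm(2000)
  scan <- univariateScan(X, y)
  expect_gt(stats::ks.test(scan$p, "punif")$p.value, 0.001)
  expect_true(all(scan$p > 0 & scan$p <= 1))
})

test_that("univariate scan recovers a single causal effect", {
  g <- simulateLocus(20000, 5, blockSpec = ldBlockSpec(5, 0), seed = 2)
  cfg <- assignEffects(g, 3, veFixed = 0.05, scenario = "1:0", seed = 3)
  y <- simulateTrait(g, cfg, seed = 4)
  scan <- univariateScan(g, y)
  expect_lt(abs(scan$beta[3] - cfg@beta), 3 * scan$se[3])
  expect_equal(which.min(scan$p), 3L)
})

test_that("a perfect linear trait gives exact beta and a floored p-value", {
  X <- matrix(c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2), ncol = 1)
  y <- 2.5 * X[, 1] + 1
  scan <- univariateScan(X, y)
  expect_equal(scan$beta[1], 2.5)
  expect_gt(scan$p[1], 0)          # underflow-guarded, never exactly 0
  expect_lt(scan$p[1], 1e-15)
})

test_that("constant variants are excluded with a flag, not an error", {
  X <- cbind(rbinom(100, 2, 0.4), rep(2, 100))
  scan <- univariateScan(X, rnorm(100))
  expect_false(scan$excluded[1])
  expect_true(scan$excluded[2])
  expect_true(is.na(scan$beta[2]))
})

test_that("stepwise detection finds independent causal pairs and stops on null", {
  # two independent causal sites, each ve = 0.1, n = 2000: power ~ 1
  set.seed(5)
  hits <- replicate(20, {
    g <- simulateLocus(2000, 20, blockSpec = ldBlockSpec(20, 0))
    cfg <- assignEffects(g, c(4, 15), veFixed = 0.1, scenario = "2:0")
    y <- simulateTrait(g, cfg)
    sw <- stepwiseConditional(g, y)
    nrow(peaks(sw)) == 2 && setequal(peaks(sw)$variantIdx, c(4, 15))
  })
  expect_gt(mean(hits), 0.9)
  # null trait: empty peak list almost always
  set.seed(6)
  empties <- replicate(30, {
    X <- matrix(rbinom(500 * 50, 2, 0.3), nrow = 500)
    nrow(peaks(stepwiseConditional(X, rnorm(500))))
  })
  expect_lt(mean(empties > 0), 0.2)
})

test_that("step one of stepwise equals the univariate scan argmin", {
  g <- simulateLocus(800, 30, seed = 7)
  cfg <- assignEffects(g, sampleCausalSet(g, 2, seed = 8), veFixed = 0.1,
                       scenario = "2:0", seed = 9)
  y <- simulateTrait(g, cfg, seed = 10)
  sw <- stepwiseConditional(g, y)
  scan <- univariateScan(g, y)
  expect_equal(peaks(sw)$variantIdx[1], which.min(scan$p))
  expect_equal(peaks(sw)$beta[1], scan$beta[which.min(scan$p)])
})

test_that("opposite effects in tight LD cancel and suppress detection", {
  # marginal effect of site 1 is beta (1 - r): near zero when r -> 1
  set.seed(11)
  det <- replicate(40, {
    g <- samplePair(1839, 0.3, 0.3, sqrt(0.9))
    cfg <- methods::new("CausalConfig", causalIdx = c(1L, 2L),
                        ve = c(0.1, 0.1), sign = c(1, -1),
                        beta = betaFromVe(c(0.1, 0.1), 0.3),
                        maf = c(0.3, 0.3), scenario = "1:1")
    y <- simulateTrait(g, cfg)
    nrow(peaks(stepwiseConditional(g, y))) >= 1
  })
  single <- univariatePower(0.1, 1839, 1e-5)
  expect_gt(single, 0.999)
  expect_lt(mean(det), 0.5)   # far below single-site power
})

test_that("joint fitting is unbiased where univariate estimates are biased", {
  set.seed(12)
  r <- sqrt(0.9)
  p <- 0.25
  beta <- betaFromVe(0.08, p)
  est <- replicate(300, {
    g <- samplePair(2000, p, p, r)
    cfg <- methods::new("CausalConfig", causalIdx = c(1L, 2L),
                        ve = c(0.08, 0.08), sign = c(1, 1),
                        beta = rep(beta, 2), maf = c(p, p),
                        scenario = "2:0")
    y <- simulateTrait(g, cfg)
    jf <- jointFit(g, y, c(1, 2))
    s <- univariateScan(g, y)
    c(joint = mean(jf@beta), uni = mean(s$beta))
  })
  # joint estimates center on the truth
  expect_equal(mean(est["joint", ]), beta, tolerance = 0.02)
  # univariate estimates carry the omitted-variable bias r * beta
  expect_equal(mean(est["uni", ]) - beta, r * beta, tolerance = 0.03)
})

test_that("single-variant joint fit equals the univariate estimate", {
  g <- simulateLocus(500, 10, seed = 13)
  y <- simulateTrait(g, assignEffects(g, 4, veFixed = 0.1,
                                      scenario = "1:0", seed = 14),
                     seed = 15)
  jf <- jointFit(g, y, 4)
  scan <- univariateScan(g, y)
  expect_equal(jf@beta, scan$beta[4], tolerance = 1e-12)
  expect_equal(jf@se, scan$se[4], tolerance = 1e-12)
})

test_that("joint fit prunes exact collinearity and rejects degenerate input", {
  set.seed(16)
  x <- rbinom(200, 2, 0.3)
  X <- cbind(x, rbinom(200, 2, 0.3), x)        # column 3 duplicates column 1
  y <- rnorm(200) + 0.5 * x
  jf <- jointFit(X, y, c(1, 2, 3))
  expect_identical(jf@pruned, 3L)
  expect_identical(jf@idx, c(1L, 2L))
  expect_error(jointFit(X[1:3, ], y[1:3], c(1, 2, 3)), "samples")
})

test_that("expected univariate bias matches the simulation oracle", {
  expect_equal(expectedUnivariateBias(0, 0.5, 0.2, 0.3), 0)
  # equal frequencies: the ratio cancels and bias = r * beta2
  expect_equal(expectedUnivariateBias(0.5, 0.4, 0.3, 0.3), 0.2)
  # frozen oracle value: r = 0.5, beta2 = 0.4, p1 = 0.2, p2 = 0.5
  expect_equal(expectedUnivariateBias(0.5, 0.4, 0.2, 0.5), 0.25,
               tolerance = 1e-12)
  set.seed(17)
  g <- samplePair(200000, 0.2, 0.5, 0.5)
  X <- dosages(g)
  y <- 0.3 * X[, 1] + 0.4 * X[, 2] + rnorm(nrow(X))
  bhat <- cov(X[, 1], y) / var(X[, 1])
  expect_equal(bhat - 0.3, 0.25, tolerance = 0.02)
  expect_error(expectedUnivariateBias(0.9, 0.4, 0.05, 0.5), "bound")
})

test_that("bias formula agrees with empirical means across an (r, p) grid", {
  set.seed(18)
  grid <- expand.grid(r = c(-0.7, -0.3, 0.3, 0.7),
                      p1 = c(0.1, 0.25, 0.5), p2 = c(0.25, 0.5))
  lo <- -sqrt(grid$p1 * grid$p2 / ((1 - grid$p1) * (1 - grid$p2)))
  hi <- mapply(maxAbsR, grid$p1, grid$p2)
  grid <- grid[grid$r >= lo & grid$r <= hi, ]
  grid <- head(grid, 12)
  for (i in seq_len(nrow(grid))) {
    r <- grid$r[i]; p1 <- grid$p1[i]; p2 <- grid$p2[i]
    g <- samplePair(20000, p1, p2, r)
    X <- dosages(g)
    y <- 0.25 * X[, 1] + 0.35 * X[, 2] + rnorm(nrow(X))
    s <- univariateScan(X[, 1, drop = FALSE], y)
    pred <- expectedUnivariateBias(cor(X[, 1], X[, 2]), 0.35, p1, p2)
    expect_lt(abs((s$beta[1] - 0.25) - pred), 3 * s$se[1])
  }
})

test_that("analytic power matches simulation and is monotone", {
  expect_equal(univariatePower(0, 1000, 0.05), 0.05, tolerance = 1e-10)
  # moderate-power point, simulated
  set.seed(19)
  n <- 800; ve <- 0.02; alpha <- 1e-3
  hits <- replicate(3000, {
    x <- rbinom(n, 2, 0.3)
    y <- betaFromVe(ve, 0.3) * x + rnorm(n)
    s <- univariateScan(matrix(x), y)
    s$p[1] < alpha
  })
  an <- univariatePower(ve, n, alpha)
  expect_lt(abs(mean(hits) - an), 3 * sqrt(an * (1 - an) / 3000))
  # monotone in n and ve
  pw <- vapply(seq(200, 2000, 300), univariatePower, numeric(1),
               ve = 0.03, alpha = 1e-5)
  expect_true(all(diff(pw) > 0))
  pv <- vapply(c(0.01, 0.03, 0.05, 0.1), univariatePower, numeric(1),
               n = 500, alpha = 1e-5)
  expect_true(all(diff(pv) > 0))
})

test_that("batch pair generation and closed-form fits match the module surface", {
  # seed-for-seed equivalence of the batch generator with samplePair
  p <- 0.3; r <- 0.6
  set.seed(20)
  d <- multisiteQTL:::.samplePairDosages(400, 1L, p, p, r)
  g <- samplePair(400, p, p, r, seed = 20)
  expect_identical(cbind(d$x1[, 1], d$x2[, 1]), unname(dosages(g)))
  # closed-form two-SNP fit equals jointFit coefficients
  set.seed(21)
  g <- samplePair(500, 0.25, 0.25, 0.7)
  X <- dosages(g)
  y <- 0.4 * X[, 1] + 0.2 * X[, 2] + rnorm(500)
  est <- multisiteQTL:::.jointFitPairBatch(X[, 1, drop = FALSE],
                                           X[, 2, drop = FALSE],
                                           matrix(y))
  jf <- jointFit(g, y, c(1, 2))
  expect_equal(unname(c(est$b1, est$b2)), unname(jf@beta), tolerance = 1e-10)
})

test_that("required sample size orders by LD and reports monotone-ish curves", {
  rs0 <- requiredSampleSize(0, 0.1, nGrid = seq(100, 700, 200),
                            reps = 150, seed = 22)
  rs9 <- requiredSampleSize(0.9, 0.1, nGrid = seq(100, 700, 200),
                            reps = 150, seed = 23)
  # the independent pair reaches 0.1 sdu far earlier (VIF ordering)
  expect_true(rs0$reached)
  expect_true(rs0$requiredN <= 300)
  expect_false(rs9$reached && rs9$requiredN <= 700)
  # error curves decrease with n (up to MC noise at these reps)
  expect_lt(tail(rs0$curve$mae, 1), rs0$curve$mae[1])
  expect_lt(tail(rs9$curve$mae, 1), rs9$curve$mae[1])
  expect_true(all(c("mae", "rmse", "sd") %in% names(rs9$curve)))
})
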