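# Genotype generators: LD feasibility bound, exact two-locus LD targets,
# block-LD locus simulation, LD matrices, causal-set sampling, file IO.

test_that("maxAbsR matches the exhaustive haplotype-table oracle", {
  expect_equal(maxAbsR(0.2, 0.2), 1.0)
  for (pq in list(c(0.1, 0.5), c(0.01, 0.5), c(0.05, 0.2), c(0.3, 0.45))) {
    expect_equal(maxAbsR(pq[1], pq[2])^2, maxR2Oracle(pq[1], pq[2]),
                 tolerance = 1e-3)
    expect_equal(maxAbsR(pq[1], pq[2]), maxAbsR(pq[2], pq[1]))
  }
  # frozen oracle values
  expect_equal(maxAbsR(0.1, 0.5)^2, 1 / 9, tolerance = 1e-6)
  expect_equal(maxAbsR(0.01, 0.5)^2, 0.010101, tolerance = 1e-4)
  expect_error(maxAbsR(0, 0.2), "maf")
  expect_error(maxAbsR(0.2, 0.6), "maf")
})

test_that("samplePair hits haplotype frequencies and empirical LD targets", {
  # p11 = p1 p2 + D: plug-in check at r = sqrt(0.9), p = 0.2
  D <- sqrt(0.9) * sqrt(0.2 * 0.8 * 0.2 * 0.8)
  expect_equal(0.2 * 0.2 + D, 0.1918, tolerance = 1e-3)
  # perfect coupling puts all mass on the 11 / 00 haplotypes
  g <- samplePair(2000, 0.5, 0.5, r = 1, seed = 1)
  X <- dosages(g)
  expect_true(all(X[, 1] == X[, 2]))
  # Monte-Carlo closure: empirical dosage r^2 near the target
  for (r2 in c(0.1, 0.5, 0.9)) {
    g <- samplePair(50000, 0.2, 0.2, sqrt(r2), seed = r2 * 100)
    expect_lt(abs(ldMatrix(g)[1, 2] - r2), 0.01)
  }
  # empirical maf within binomial sampling error of the request
  g <- samplePair(50000, 0.1, 0.3, 0.2, seed = 7)
  expect_equal(unname(mafs(g)), c(0.1, 0.3),
               tolerance = 4 * sqrt(0.3 * 0.7 / 1e5) / 0.1)
})

test_that("samplePair rejects infeasible LD targets by naming the bound", {
  expect_error(samplePair(100, 0.1, 0.5, 0.5), "infeasible")
  expect_error(samplePair(100, 0.01, 0.5, -0.2), "infeasible")
})

test_that("haplotype frequencies stay valid over random feasible draws", {
  set.seed(42)
  for (i in 1:200) {
    p1 <- runif(1, 0.01, 0.5)
    p2 <- runif(1, 0.01, 0.5)
    lo <- -sqrt(p1 * p2 / ((1 - p1) * (1 - p2)))
    r <- runif(1, lo, maxAbsR(p1, p2))
    g <- samplePair(20, p1, p2, r)
    expect_true(all(dosages(g) %in% 0:2))
  }
  # repulsion beyond the joint-mass bound is rejected
  expect_error(samplePair(100, 0.1, 0.1, -0.5), "infeasible")
})

test_that("generators are deterministic under a fixed seed", {
  g1 <- samplePair(500, 0.2, 0.3, 0.4, seed = 11)
  g2 <- samplePair(500, 0.2, 0.3, 0.4, seed = 11)
  expect_identical(dosages(g1), dosages(g2))
  l1 <- simulateLocus(200, 30, seed = 12)
  l2 <- simulateLocus(200, 30, seed = 12)
  expect_identical(dosages(l1), dosages(l2))
  expect_identical(variantPositions(l1), variantPositions(l2))
})

test_that("simulateLocus injects block LD and respects the independence baseline", {
  # rho = 0: mean off-diagonal r^2 near the 1/(n-1) independence baseline
  g0 <- simulateLocus(400, 40, blockSpec = ldBlockSpec(40, 0), seed = 3)
  r2 <- ldMatrix(g0)
  off <- r2[upper.tri(r2)]
  expect_lt(mean(off), 3 / (400 - 1))
  # high rho: adjacent pairs in tighter LD than distant pairs
  g1 <- simulateLocus(400, 40, blockSpec = ldBlockSpec(40, 0.95), seed = 4)
  r2 <- ldMatrix(g1)
  adj <- r2[cbind(1:39, 2:40)]
  far <- r2[cbind(1:20, 21:40)]
  expect_gt(median(adj), median(far))
  # all variants polymorphic, positions strictly increasing on 400 kb
  expect_true(all(apply(dosages(g1), 2, sd) > 0))
  expect_true(all(diff(variantPositions(g1)) > 0))
  expect_lte(max(variantPositions(g1)), 400000)
})

test_that("maf spectra respect their bounds and bin masses sum to one", {
  for (kind in c("uniform_range", "rare_shifted")) {
    sp <- mafSpectrum(kind)
    x <- sampleMaf(sp, 5000, seed = 5)
    expect_true(all(x >= sp$floor & x <= sp$ceiling))
    mass <- mafBinMass(sp, c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5))
    expect_equal(sum(mass), 1)
  }
  # rare-shifted mode sits near maf 0.02
  sp <- mafSpectrum("rare_shifted")
  d <- density(sampleMaf(sp, 2e4, seed = 6), from = 0.01, to = 0.5)
  expect_lt(d$x[which.max(d$y)], 0.04)
})

test_that("ldMatrix is sign-invariant and flags constant columns", {
  X <- cbind(a = c(0, 1, 2, 1, 0, 2), b = c(0, 1, 2, 1, 0, 2))
  expect_equal(ldMatrix(X)[1, 2], 1)
  Xc <- cbind(X[, 1], 2 - X[, 1])   # complement allele coding
  expect_equal(ldMatrix(Xc)[1, 2], 1)
  Xbad <- cbind(X, k = rep(1, 6))
  expect_warning(r2 <- ldMatrix(Xbad), "constant")
  expect_identical(attr(r2, "excluded"), 3L)
  expect_equal(dim(r2), c(2L, 2L))
})

test_that("sampleCausalSet honors constraints or fails loudly", {
  g <- simulateLocus(300, 50, seed = 21)
  idx <- sampleCausalSet(g, 4, seed = 22)
  expect_length(idx, 4)
  expect_false(anyDuplicated(idx) > 0)
  # constrained draw inside a high-LD block
  gh <- simulateLocus(800, 20, blockSpec = ldBlockSpec(20, 0.99), seed = 23)
  idx <- sampleCausalSet(gh, 3, constraint = "pairwise_r2_min",
                         r2Min = 0.3, seed = 24)
  r2 <- ldMatrix(gh, idx)
  expect_true(all(r2[upper.tri(r2)] > 0.3))
  # unsatisfiable constraint on an independent panel
  gi <- simulateLocus(300, 20, blockSpec = ldBlockSpec(20, 0), seed = 25)
  expect_error(
    sampleCausalSet(gi, 3, constraint = "pairwise_r2_min", r2Min = 0.99,
                    maxTries = 50, seed = 26),
    "tries")
})

test_that("VCF genotypes read as minor-allele dosages with maf filtering", {
  path <- tempfile(fileext = ".vcf")
  gt <- rbind(
    c("0/0", "0/1", "1/1", "0/1", "0/0", "0/0", "0/1", "0/0", "0/0", "0/0"),
    c("1/1", "1/1", "0/1", "1/1", "1/1", "1/1", "1/1", "1/1", "1/1", "0/1"),
    c("0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/1"))
  writeTestVcf(path, gt, c("rs1", "rs2", "rs3"), c(1000, 2000, 3000))
  expect_message(g <- readGenotypes(path, "vcf", mafFloor = 0.06),
                 "dropped 1")
  expect_equal(nVariants(g), 2L)
  # rs1 counted toward the alternate (minor) allele directly
  expect_equal(unname(dosages(g)[, "rs1"]),
               c(0, 1, 2, 1, 0, 0, 1, 0, 0, 0))
  # rs2 is flipped: the reference allele is minor
  expect_equal(unname(dosages(g)[, "rs2"]),
               2 - c(2, 2, 1, 2, 2, 2, 2, 2, 2, 1))
  expect_true(all(mafs(g) <= 0.5))
})

test_that("dosage TSV round-trips through write and read", {
  g <- simulateLocus(40, 8, seed = 31)
  path <- tempfile(fileext = ".tsv")
  paths <- writeDosageTsv(g, path)
  g2 <- readGenotypes(path, "dosage_tsv", metadata = paths[2],
                      mafFloor = 0.001)
  expect_equal(unname(dosages(g2)), unname(dosages(g)))
  expect_equal(unname(variantPositions(g2)), unname(variantPositions(g)))
  expect_equal(variantIds(g2), variantIds(g))
})

test_that("missing genotypes are rejected or mean-imputed by threshold", {
  path <- tempfile(fileext = ".vcf")
  gt <- rbind(
    c("0/1", "./.", "0/0", "1/1", "0/1", "0/0", "0/1", "0/0", "0/1", "0/0"),
    c("0/1", "0/0", "1/1", "0/1", "0/0", "0/1", "0/0", "0/1", "0/0", "0/1"))
  writeTestVcf(path, gt, c("rs1", "rs2"), c(1, 2))
  expect_warning(g <- readGenotypes(path, "vcf", maxMissing = 0.2),
                 "imputing")
  expect_equal(nVariants(g), 2L)
  expect_error(
    suppressWarnings(readGenotypes(path, "vcf", maxMissing = 0.05)),
    "missingness")
})

test_that("GenotypePanel validity enforces its invariants", {
  g <- tinyPanel()
  expect_equal(nSamples(g), 6L)
  expect_equal(nVariants(g), 3L)
  expect_true(all(mafs(g) > 0 & mafs(g) <= 0.5))
  expect_error(GenotypePanel(matrix(c(0, 3), 2, 1)))
  expect_error(GenotypePanel(matrix(0:1, 2, 2), positions = c(5, 5)))
})
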