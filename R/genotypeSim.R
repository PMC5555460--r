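# Genotype simulation: two-locus haplotype construction with exact LD
# targets, and a latent-Gaussian block model for whole-locus panels.

.setSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

.checkMaf <- function(p, what = "maf") {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 0.5))
    stop(what, " must lie in (0, 0.5], got ", paste(p, collapse = ", "),
         call. = FALSE)
  invisible(p)
}

#' Maximum attainable |r| between two loci given their allele frequencies
#'
#' Linkage disequilibrium between a rare and a common variant is bounded:
#' with minor alleles coupled, the largest achievable correlation is
#' `sqrt(pmin (1 - pmax) / (pmax (1 - pmin)))` where `pmin`/`pmax` are the
#' smaller and larger of the two minor allele frequencies. High r-squared is
#' therefore only possible for frequency-matched pairs.
#'
#' @param p1,p2 minor allele frequencies in (0, 0.5].
#' @return The maximum attainable `|r|`, in (0, 1]. Symmetric in `p1`, `p2`.
#' @examples
#' maxAbsR(0.2, 0.2)        # 1: equal frequencies permit perfect LD
#' maxAbsR(0.1, 0.5)^2      # ~0.111: best r^2 for a 0.1/0.5 pair
#' @export
maxAbsR <- function(p1, p2) {
  .checkMaf(c(p1, p2))
  pmin_ <- min(p1, p2)
  pmax_ <- max(p1, p2)
  sqrt(pmin_ * (1 - pmax_) / (pmax_ * (1 - pmin_)))
}

# Signed feasibility interval for the haplotype correlation r: coupling
# (r > 0) is bounded by the frequency-mismatch term, repulsion (r < 0) by
# the joint minor-haplotype mass.
.rBounds <- function(p1, p2) {
  c(lo = -sqrt(p1 * p2 / ((1 - p1) * (1 - p2))), hi = maxAbsR(p1, p2))
}

# Two-locus haplotype frequencies (p11, p10, p01, p00) for coupled minor
# alleles at signed correlation r.
.pairHapFreqs <- function(p1, p2, r) {
  D <- r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  f <- c(p11 = p1 * p2 + D, p10 = p1 * (1 - p2) - D,
         p01 = (1 - p1) * p2 - D, p00 = (1 - p1) * (1 - p2) + D)
  # clamp tiny negative rounding at the feasibility boundary
  if (any(f < -1e-9)) stop("internal: negative haplotype frequency")
  pmax(f, 0)
}

# Batch two-locus dosage generator: n samples x reps replicates.
# Returns list(x1, x2) of n x reps integer dosage matrices. Haplotypes are
# iid multinomial draws; random pairing of haplotypes into diplotypes is
# equivalent to pairing consecutive iid draws.
.samplePairDosages <- function(nSamples, reps, p1, p2, r) {
  f <- .pairHapFreqs(p1, p2, r)
  h <- sample.int(4L, 2L * nSamples * reps, replace = TRUE, prob = f)
  a1 <- h <= 2L                 # minor allele at locus 1 (types p11, p10)
  a2 <- h == 1L | h == 3L       # minor allele at locus 2 (types p11, p01)
  odd <- seq(1L, 2L * nSamples * reps, by = 2L)
  x1 <- matrix(a1[odd] + a1[odd + 1L], nrow = nSamples)
  x2 <- matrix(a2[odd] + a2[odd + 1L], nrow = nSamples)
  list(x1 = x1, x2 = x2)
}

#' Simulate a two-variant genotype panel with an exact LD target
#'
#' Builds the two-locus haplotype frequency table with
#' `p11 = p1 p2 + D`, `D = r sqrt(p1 (1 - p1) p2 (1 - p2))`, draws `2 n`
#' haplotypes multinomially and pairs them at random into diploid dosage
#' genotypes. The signed haplotype correlation `r` equals the expected
#' dosage correlation under random pairing.
#'
#' @param nSamples number of diploid samples.
#' @param p1,p2 minor allele frequencies in (0, 0.5].
#' @param r signed target haplotype correlation. Positive `r` (minor
#'   alleles coupled) is bounded by [maxAbsR()]; negative `r` (repulsion)
#'   is bounded by `-sqrt(p1 p2 / ((1 - p1)(1 - p2)))`, since the doubly
#'   minor haplotype frequency cannot drop below zero.
#' @param seed optional integer seed.
#' @return A [GenotypePanel-class] with two variants.
#' @examples
#' g <- samplePair(500, 0.2, 0.2, sqrt(0.5), seed = 1)
#' ldMatrix(g)[1, 2]   # close to 0.5
#' @export
samplePair <- function(nSamples, p1, p2, r, seed = NULL) {
  .checkMaf(c(p1, p2))
  b <- .rBounds(p1, p2)
  if (r > b["hi"] + 1e-12 || r < b["lo"] - 1e-12)
    stop("r = ", r, " is infeasible for maf (", p1, ", ", p2,
         "): r must lie in [", signif(b["lo"], 6), ", ",
         signif(b["hi"], 6), "]", call. = FALSE)
  .setSeed(seed)
  # at small n a rare column can come out monomorphic; redraw (the
  # distribution conditions on both loci being polymorphic)
  for (try in 1:1000) {
    d <- .samplePairDosages(nSamples, 1L, p1, p2, r)
    if (length(unique(d$x1[, 1L])) > 1L && length(unique(d$x2[, 1L])) > 1L)
      break
  }
  if (length(unique(d$x1[, 1L])) == 1L) d$x1[1L, 1L] <- 1L
  if (length(unique(d$x2[, 1L])) == 1L) d$x2[1L, 1L] <- 1L
  GenotypePanel(cbind(d$x1[, 1L], d$x2[, 1L]),
                positions = c(100000L, 300000L),
                variantIds = c("snpA", "snpB"))
}

#' Specify the LD block structure of a simulated locus
#'
#' Describes a locus as consecutive blocks of variants; within a block the
#' latent haplotype field follows a first-order autoregression with
#' parameter `withinBlockRho` (serial correlation of adjacent variants),
#' and distinct blocks are independent. The default layout for `nSnps`
#' variants mimics a locus with two large and one small block of elevated
#' LD separated by low-LD spacers.
#'
#' @param blockLengths integer vector of variants per block; must sum to the
#'   number of simulated variants.
#' @param withinBlockRho per-block latent AR parameter in \[0, 1); recycled.
#' @return An object of class `LDBlockSpec` (a validated list).
#' @examples
#' ldBlockSpec(c(40, 5, 20, 5, 30), c(0.97, 0, 0.95, 0, 0.97))
#' @export
ldBlockSpec <- function(blockLengths, withinBlockRho = 0.95) {
  blockLengths <- as.integer(blockLengths)
  stopifnot(all(blockLengths >= 1L))
  withinBlockRho <- rep_len(withinBlockRho, length(blockLengths))
  if (any(withinBlockRho < 0) || any(withinBlockRho >= 1))
    stop("withinBlockRho must lie in [0, 1)", call. = FALSE)
  structure(list(blockLengths = blockLengths,
                 withinBlockRho = withinBlockRho,
                 betweenBlockRho = 0),
            class = "LDBlockSpec")
}

#' @rdname ldBlockSpec
#' @param nSnps number of variants to lay out with the default block plan.
#' @export
defaultBlockSpec <- function(nSnps) {
  stopifnot(nSnps >= 1L)
  if (nSnps < 10L) return(ldBlockSpec(nSnps, 0.95))
  # two large high-LD blocks and one small one, separated by low-LD spacers
  big <- floor(nSnps * 0.35)
  small <- max(floor(nSnps * 0.1), 1L)
  spacer <- nSnps - 2L * big - small
  s1 <- spacer %/% 2L
  s2 <- spacer - s1
  len <- c(big, s1, small, s2, big)
  rho <- c(0.995, 0.3, 0.99, 0.3, 0.995)
  keep <- len > 0L
  ldBlockSpec(len[keep], rho[keep])
}

#' Specify a minor allele frequency spectrum
#'
#' Two spectra are supported: `"uniform_range"` (maf uniform between
#' `floor` and `ceiling`, the common-variant universe) and `"rare_shifted"`
#' (a scaled Beta density concentrated near its mode, emulating the
#' frequency spectrum of variants absent from an imputation panel, which is
#' strongly shifted toward rare alleles with mode about 0.02).
#'
#' @param kind `"uniform_range"` or `"rare_shifted"`.
#' @param floor,ceiling bounds of the spectrum support, default 0.01 / 0.5.
#' @param shape1,shape2 Beta shape parameters for `"rare_shifted"`; defaults
#'   place the mode of the mapped density at maf 0.02.
#' @return An object of class `MafSpectrum`.
#' @examples
#' sp <- mafSpectrum("rare_shifted")
#' summary(sampleMaf(sp, 1000, seed = 1))
#' @export
mafSpectrum <- function(kind = c("uniform_range", "rare_shifted"),
                        floor = 0.01, ceiling = 0.5,
                        shape1 = 1.4, shape2 = 24) {
  kind <- match.arg(kind)
  stopifnot(floor > 0, ceiling <= 0.5, floor < ceiling)
  structure(list(kind = kind, floor = floor, ceiling = ceiling,
                 shape1 = shape1, shape2 = shape2),
            class = "MafSpectrum")
}

#' @rdname mafSpectrum
#' @param spec a `MafSpectrum`.
#' @param n number of frequencies to draw.
#' @param seed optional integer seed.
#' @export
sampleMaf <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "MafSpectrum"))
  .setSeed(seed)
  quantileMaf(spec, runif(n))
}

#' @rdname mafSpectrum
#' @param prob probabilities in \[0, 1\] to map through the spectrum's
#'   quantile function.
#' @export
quantileMaf <- function(spec, prob) {
  stopifnot(inherits(spec, "MafSpectrum"))
  u <- switch(spec$kind,
    uniform_range = prob,
    rare_shifted = stats::qbeta(prob, spec$shape1, spec$shape2))
  spec$floor + (spec$ceiling - spec$floor) * u
}

#' @rdname mafSpectrum
#' @param edges increasing maf bin edges spanning part of the support.
#' @return `mafBinMass()`: the probability mass of each bin under the
#'   spectrum, normalized to the mass of the covered range.
#' @export
mafBinMass <- function(spec, edges) {
  stopifnot(inherits(spec, "MafSpectrum"), length(edges) >= 2L,
            all(diff(edges) > 0))
  z <- (pmin(pmax(edges, spec$floor), spec$ceiling) - spec$floor) /
    (spec$ceiling - spec$floor)
  cdf <- switch(spec$kind,
    uniform_range = z,
    rare_shifted = pbeta(z, spec$shape1, spec$shape2))
  mass <- diff(cdf)
  mass / sum(mass)
}

#' Simulate a genotype panel for a gene locus with block LD
#'
#' Haplotypes are generated from a latent Gaussian field with first-order
#' serial correlation within LD blocks (independent across blocks) and
#' dichotomized at the per-variant maf quantile; pairs of haplotypes form
#' diploid dosages. Variant positions are drawn uniformly over `span` base
#' pairs (default 400 kb, a typical cis-window extending 200 kb on either
#' side of a gene). Columns that come out monomorphic are resampled
#' independently of the block structure.
#'
#' @param nSamples,nSnps panel dimensions.
#' @param blockSpec an [ldBlockSpec()]; default [defaultBlockSpec()]`(nSnps)`.
#' @param mafSpec a [mafSpectrum()]; default uniform on (0.01, 0.5).
#' @param span locus length in base pairs.
#' @param seed optional integer seed.
#' @return A [GenotypePanel-class].
#' @examples
#' g <- simulateLocus(200, 50, seed = 1)
#' g
#' @export
simulateLocus <- function(nSamples, nSnps, blockSpec = NULL, mafSpec = NULL,
                          span = 400000L, seed = NULL) {
  .setSeed(seed)
  raw <- .simulateLocusRaw(nSamples, nSnps, blockSpec, mafSpec, span)
  GenotypePanel(raw$dosages, positions = raw$positions,
                variantIds = sprintf("snp%04d", seq_len(nSnps)))
}

# Matrix-level locus generator (no S4 wrapping); uses the current RNG
# stream. Returns list(dosages, positions).
.simulateLocusRaw <- function(nSamples, nSnps, blockSpec = NULL,
                              mafSpec = NULL, span = 400000L) {
  stopifnot(nSnps >= 1L, nSamples >= 2L)
  if (is.null(blockSpec)) blockSpec <- defaultBlockSpec(nSnps)
  if (is.null(mafSpec)) mafSpec <- mafSpectrum("uniform_range")
  if (sum(blockSpec$blockLengths) != nSnps)
    stop("blockLengths must sum to nSnps", call. = FALSE)
  nh <- 2L * nSamples
  z <- matrix(rnorm(nh * nSnps), nrow = nh)
  v <- rnorm(nSnps)    # latent field for maf (frequencies cluster in blocks)
  # AR(1) within blocks: z_j = rho z_{j-1} + sqrt(1 - rho^2) eps_j
  j0 <- 0L
  for (b in seq_along(blockSpec$blockLengths)) {
    len <- blockSpec$blockLengths[b]
    rho <- blockSpec$withinBlockRho[b]
    if (len > 1L && rho > 0) {
      for (j in 2:len) {
        z[, j0 + j] <- rho * z[, j0 + j - 1L] +
          sqrt(1 - rho^2) * z[, j0 + j]
        v[j0 + j] <- rho * v[j0 + j - 1L] + sqrt(1 - rho^2) * v[j0 + j]
      }
    }
    j0 <- j0 + len
  }
  # variants in strong LD share ancestry, hence similar frequencies; the
  # marginal maf distribution is exactly the requested spectrum
  maf <- quantileMaf(mafSpec, pnorm(v))
  thr <- qnorm(maf)
  alleles <- sweep(z, 2L, thr, "<")        # TRUE = minor allele
  # resample monomorphic columns (independent of the LD field)
  cs <- colSums(alleles)
  for (j in which(cs == 0L | cs == nh)) {
    tries <- 0L
    while (tries < 100L) {
      alleles[, j] <- rnorm(nh) < thr[j]
      s <- sum(alleles[, j])
      if (s > 0L && s < nh) break
      tries <- tries + 1L
    }
    s <- sum(alleles[, j])
    if (s == 0L || s == nh)
      alleles[sample.int(nh, 1L), j] <- !alleles[1L, j]
  }
  odd <- seq(1L, nh, by = 2L)
  dos <- alleles[odd, , drop = FALSE] + alleles[odd + 1L, , drop = FALSE]
  storage.mode(dos) <- "integer"
  list(dosages = dos, positions = sort(sample.int(span, nSnps)))
}

#' Pairwise LD (r-squared) matrix of dosage columns
#'
#' LD is measured as the squared Pearson correlation of minor-allele dosage
#' columns — the quantity conditional regression actually "sees". Constant
#' columns cannot be correlated and are excluded with a warning; their
#' indices are attached as attribute `"excluded"`.
#'
#' @param G a [GenotypePanel-class] or a numeric samples-by-variants matrix.
#' @param idx optional variant subset (indices into the panel columns).
#' @return A symmetric r-squared matrix with unit diagonal.
#' @examples
#' g <- samplePair(400, 0.3, 0.3, 0.9, seed = 1)
#' ldMatrix(g)
#' @export
ldMatrix <- function(G, idx = NULL) {
  X <- if (methods::is(G, "GenotypePanel")) dosages(G) else as.matrix(G)
  if (!is.null(idx)) X <- X[, idx, drop = FALSE]
  sds <- apply(X, 2L, sd)
  bad <- as.integer(which(sds == 0))
  if (length(bad)) {
    warning("excluding ", length(bad), " constant column(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
    X <- X[, -bad, drop = FALSE]
  }
  r2 <- cor(X)^2
  diag(r2) <- 1
  attr(r2, "excluded") <- bad
  r2
}

#' Sample a set of causal variant indices from a panel
#'
#' Draws `k` distinct variant columns uniformly; under the
#' `"pairwise_r2_min"` constraint, redraws until every pair in the set has
#' dosage r-squared above `r2Min` (used to study fine mapping of several
#' causal sites inside one high-LD block). The retry budget is explicit:
#' exhausting it raises an error rather than silently relaxing the
#' constraint.
#'
#' @param G a [GenotypePanel-class].
#' @param k number of causal sites.
#' @param constraint `"none"` or `"pairwise_r2_min"`.
#' @param r2Min pairwise r-squared threshold for the constrained draw.
#' @param maxTries retry budget for the constrained draw.
#' @param seed optional integer seed.
#' @return Integer vector of `k` distinct column indices.
#' @examples
#' g <- simulateLocus(200, 50, seed = 1)
#' sampleCausalSet(g, 4, seed = 2)
#' @export
sampleCausalSet <- function(G, k, constraint = c("none", "pairwise_r2_min"),
                            r2Min = 0.3, maxTries = 1000L, seed = NULL) {
  constraint <- match.arg(constraint)
  m <- nVariants(G)
  stopifnot(k >= 1L, k <= m)
  .setSeed(seed)
  if (constraint == "none") return(sort(sample.int(m, k)))
  X <- dosages(G)
  for (i in seq_len(maxTries)) {
    idx <- sort(sample.int(m, k))
    r2 <- cor(X[, idx, drop = FALSE])^2
    if (all(r2[upper.tri(r2)] > r2Min)) return(idx)
  }
  stop("could not find ", k, " variants with all pairwise r^2 > ", r2Min,
       " in ", maxTries, " tries", call. = FALSE)
}
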