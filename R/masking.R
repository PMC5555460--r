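# The untyped-causal-variant ("masking") experiment: simulate a causal
# site, delete it and its close proxies from the panel, and measure how
# often stepwise analysis splits the orphaned signal into spurious
# secondary associations.

#' Remove a causal variant and its close proxies from a panel
#'
#' Deletes the causal column and every column with dosage r-squared above
#' `r2Cut` to it, emulating a causal variant that is absent from the
#' imputation panel together with its best tags.
#'
#' @param G a [GenotypePanel-class].
#' @param causalIdx the causal variant's column index.
#' @param r2Cut masking LD cutoff in \[0, 1\] (default 0.8; 0 removes every
#'   correlated column and is almost always degenerate).
#' @return A list: `panel` (the reduced [GenotypePanel-class]),
#'   `removedIds`, `removedIdx`, and `bestRemainingR2` (the strongest
#'   remaining proxy's r-squared with the removed causal). Emptying the
#'   panel entirely is an error.
#' @export
maskTagged <- function(G, causalIdx, r2Cut = 0.8) {
  stopifnot(r2Cut >= 0, r2Cut <= 1,
            causalIdx >= 1L, causalIdx <= nVariants(G))
  X <- dosages(G)
  xc <- X[, causalIdx]
  if (sd(xc) == 0) stop("causal column is constant", call. = FALSE)
  r2 <- suppressWarnings(as.vector(cor(xc, X))^2)
  r2[is.na(r2)] <- 0
  drop <- which(r2 > r2Cut | seq_len(ncol(X)) == causalIdx)
  if (length(drop) == ncol(X))
    stop("masking at r^2 > ", r2Cut, " removes the entire panel",
         call. = FALSE)
  keep <- setdiff(seq_len(ncol(X)), drop)
  list(panel = G[keep, ], removedIds = variantIds(G)[drop],
       removedIdx = drop, bestRemainingR2 = max(r2[keep]))
}

#' Expected best-proxy tagging as a function of maf
#'
#' A declared parametric stand-in for the tagging efficiency of untyped
#' variants by an imputed panel: the expected r-squared between an untyped
#' variant and its best typed proxy rises roughly linearly in log10 maf,
#' exceeding 0.7 above maf 0.05 and plateauing near `cap` for common
#' variants. Rare untyped variants are mostly near-untagged — rare alleles
#' arise on single haplotype backgrounds and the similarly-rare variants
#' that could tag them well are usually absent from the typed panel too —
#' so the curve's rare end sits low enough that most maf-0.01 causal
#' effects generate no detectable signal at all.
#'
#' @param maf minor allele frequency (vectorized).
#' @param intercept expected value at maf 0.01.
#' @param slope increase per decade of maf.
#' @param cap upper plateau.
#' @return Expected best-proxy r-squared, in (0, `cap`\].
#' @examples
#' taggingCurve(c(0.01, 0.02, 0.05, 0.2))
#' @export
taggingCurve <- function(maf, intercept = 0.05, slope = 0.85, cap = 0.9) {
  .checkMaf(maf)
  pmax(0.03, pmin(cap, intercept + slope * (log10(maf) + 2)))
}

# Build a locus around one causal variant, on a latent
# haplotype-background coordinate u in [0, 1). Three proxy types mimic the
# population genetics of tagging:
#  * mosaic tags (common causals): near-frequency variants that cover a
#    proxy-specific interval of carrier backgrounds (and gain false
#    carriers on another) — complementary carrier coverage is what lets
#    stepwise analysis split one untyped signal into several;
#  * ancestral tags (rare causals): higher-maf supersets of the carrier
#    lineage — young rare alleles sit on a single haplotype background,
#    so their typed tags contain the lineage, cap r^2 low, and cannot
#    split the signal;
#  * sub-lineage markers: lower-maf variants carried by a contiguous
#    subset of carrier backgrounds, present in the typed panel only when
#    their own maf clears the panel floor (hence absent for rare
#    causals).
# The tag hierarchy is sparse: one best tag at topR2, a second tier at a
# random fraction of it, and the rest below the second tier, leaving the
# irregular gaps seen at real loci.
.buildTaggedLocus <- function(nSamples, causalMaf, topR2, nProxies) {
  nh <- 2L * nSamples
  pc <- causalMaf
  h <- runif(nh) < pc
  u <- runif(nh)                       # haplotype background rank
  tier2 <- runif(1L, 0.15, 1)
  r2lad <- topR2 * c(1, tier2, runif(nProxies - 2L, 0.05, tier2))
  wAncestral <- max(0, 1 - pc / 0.15)  # rare alleles: lineage-type tags
  cols <- matrix(FALSE, nh, nProxies)
  for (j in seq_len(nProxies)) {
    if (j > 1L && j %% 3L == 0L) {
      # sub-lineage marker; r^2 with the causal is L(1-pc)/(1-L pc),
      # capped at topR2 so no marker outtags the locus's tagging level
      Lmax <- min(0.9, topR2 / (1 - pc + topR2 * pc))
      L <- if (Lmax > 0.2) runif(1L, 0.2, Lmax) else Lmax
      if (L * pc >= 0.011) {
        o <- runif(1L)
        cols[, j] <- h & (((u - o) %% 1) < L)
        next
      }
    }
    if (runif(1L) < wAncestral) {
      # ancestral superset: p_j solves r^2 = pc (1-p_j) / (p_j (1-pc))
      r2 <- max(r2lad[j], pc / (1 - pc) * 1.0001)
      pj <- min(0.5, pc / (r2 * (1 - pc) + pc))
      e <- (pj - pc) / (1 - pc)
      o <- runif(1L)
      cols[, j] <- h | (!h & (((u - o) %% 1) < e))
    } else {
      # mosaic tag with its own maf near (not equal to) the causal's;
      # the attainable r is capped by the frequency mismatch
      pj <- min(0.5, max(0.011, pc * exp(runif(1L, -0.5, 0.5))))
      r <- min(sqrt(r2lad[j]), 0.97 * maxAbsR(pc, pj))
      p11 <- pc * pj + r * sqrt(pc * (1 - pc) * pj * (1 - pj))
      a <- p11 / pc                    # P(tag | carrier)
      b <- (pj - p11) / (1 - pc)       # P(tag | non-carrier)
      o <- runif(1L)
      d <- (u - o) %% 1
      cols[, j] <- ifelse(h, d < a, d < b)
    }
  }
  odd <- seq(1L, nh, by = 2L)
  allele <- cbind(h, cols)
  dos <- allele[odd, , drop = FALSE] + allele[odd + 1L, , drop = FALSE]
  # guard monomorphic columns (possible for rare maf at small n)
  for (j in seq_len(ncol(dos))) {
    if (length(unique(dos[, j])) == 1L)
      dos[sample.int(nSamples, 2L), j] <- c(1L, 1L)
  }
  GenotypePanel(dos, positions = seq_len(ncol(dos)) * 1000L,
                variantIds = c("causal", sprintf("proxy%02d",
                                                 seq_len(nProxies))))
}

#' Run one masked-causal trial
#'
#' Draws a causal maf from the spectrum, builds a locus whose best proxy
#' tags the causal at the level typical for that maf (per
#' [taggingCurve()], with jitter), simulates the trait, removes the causal
#' and all proxies above the mask cutoff, and runs stepwise detection on
#' the reduced panel. A primary signal is any detection; a secondary
#' signal (two or more peaks for one true causal site) is spurious by
#' construction.
#'
#' @param nSamples sample size (default 1839).
#' @param mafSpec a [mafSpectrum()]; default `"rare_shifted"`, emulating
#'   the unimputed-variant frequency spectrum.
#' @param veRange uniform VE range for the causal effect (default
#'   0.02-0.10).
#' @param alpha stepwise threshold (default `1e-5`).
#' @param maskCut masking LD cutoff (default 0.8; 0.5 is also of interest).
#' @param nProxies number of proxy variants in the locus.
#' @param mask set `FALSE` for the control mode in which the causal stays
#'   in the panel.
#' @param seed optional integer seed.
#' @return A one-row data.frame (a `MaskTrial`): `causalMaf`, `ve`,
#'   `bestRemainingProxyR2`, `primaryDetected`, `secondaryDetected`,
#'   `nPeaks`, `seed`.
#' @export
spuriousSignalTrial <- function(nSamples = 1839L, mafSpec = NULL,
                                veRange = c(0.02, 0.10), alpha = 1e-5,
                                maskCut = 0.8, nProxies = 24L,
                                mask = TRUE, seed = NULL) {
  if (is.null(mafSpec)) mafSpec <- mafSpectrum("rare_shifted")
  .setSeed(seed)
  causalMaf <- sampleMaf(mafSpec, 1L)
  # per-locus best-proxy tagging: Beta-distributed around the expected
  # curve (precision 6), reflecting the wide locus-to-locus spread in how
  # well an untyped variant is tagged
  mu <- taggingCurve(causalMaf)
  top <- min(0.95, max(0.02, stats::rbeta(1L, mu * 6, (1 - mu) * 6)))
  G <- .buildTaggedLocus(nSamples, causalMaf, top, nProxies)
  ve <- runif(1L, veRange[1L], veRange[2L])
  cfg <- assignEffects(G, 1L, veFixed = ve, scenario = "1:0")
  y <- simulateTrait(G, cfg)
  if (mask) {
    mk <- maskTagged(G, 1L, r2Cut = maskCut)
    panel <- mk$panel
    bestR2 <- mk$bestRemainingR2
  } else {
    panel <- G
    bestR2 <- 1
  }
  sw <- stepwiseConditional(panel, y, alpha = alpha)
  np <- nrow(peaks(sw))
  data.frame(causalMaf = causalMaf, ve = ve,
             bestRemainingProxyR2 = bestR2,
             primaryDetected = np >= 1L,
             secondaryDetected = np >= 2L,
             nPeaks = np,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Aggregate masked-causal trials by maf bin
#'
#' Computes per-bin primary and secondary detection rates with exact
#' binomial confidence intervals, weights each bin by its mass under the
#' maf spectrum, and sums rate times weight into the cumulative weighted
#' proportion of spurious secondary signals.
#'
#' @param trials data.frame of rows from [spuriousSignalTrial()].
#' @param binEdges maf bin edges (default `c(0.01, 0.02, 0.05, 0.1, 0.2,
#'   0.5)`).
#' @param mafSpec the [mafSpectrum()] supplying bin weights (default
#'   `"rare_shifted"`, matching the trial default).
#' @return A list of class `SpuriousSignalSummary`: `bins` (per-bin n,
#'   rates, CIs, weight), `cumulativeSpuriousProportion`, and `emptyBins`.
#' @export
aggregateByMafBin <- function(trials, binEdges = c(0.01, 0.02, 0.05,
                                                   0.1, 0.2, 0.5),
                              mafSpec = NULL) {
  if (is.null(mafSpec)) mafSpec <- mafSpectrum("rare_shifted")
  stopifnot(nrow(trials) >= 1L, all(diff(binEdges) > 0))
  b <- cut(trials$causalMaf, binEdges, include.lowest = TRUE)
  w <- mafBinMass(mafSpec, binEdges)
  lev <- levels(b)
  rows <- lapply(seq_along(lev), function(i) {
    sel <- which(b == lev[i])
    n <- length(sel)
    if (!n) {
      return(data.frame(bin = lev[i], n = 0L, primaryRate = NA_real_,
                        primaryLo = NA_real_, primaryHi = NA_real_,
                        secondaryRate = NA_real_, secondaryLo = NA_real_,
                        secondaryHi = NA_real_, weight = w[i]))
    }
    pr <- sum(trials$primaryDetected[sel])
    sr <- sum(trials$secondaryDetected[sel])
    pci <- stats::binom.test(pr, n)$conf.int
    sci <- stats::binom.test(sr, n)$conf.int
    data.frame(bin = lev[i], n = n, primaryRate = pr / n,
               primaryLo = pci[1L], primaryHi = pci[2L],
               secondaryRate = sr / n, secondaryLo = sci[1L],
               secondaryHi = sci[2L], weight = w[i])
  })
  bins <- do.call(rbind, rows)
  nonEmpty <- bins$n > 0L
  cum <- sum(bins$secondaryRate[nonEmpty] * bins$weight[nonEmpty])
  structure(list(bins = bins, cumulativeSpuriousProportion = cum,
                 emptyBins = bins$bin[!nonEmpty],
                 binEdges = binEdges),
            class = "SpuriousSignalSummary")
}

#' Project a genome-wide count of spurious secondary associations
#'
#' A pure arithmetic helper: multiplies the cumulative weighted spurious
#' proportion by the number of untyped variants, the fraction of them in
#' genic windows, and the fraction assumed functional. All constants are
#' user-supplied; the defaults reflect common round numbers for a
#' 1000G-imputed European-ancestry panel.
#'
#' @param cumulativeProportion cumulative weighted spurious proportion
#'   (e.g. from [aggregateByMafBin()]).
#' @param nUntyped number of untyped (unimputed) variants.
#' @param genicFraction fraction within gene windows.
#' @param functionalFraction fraction assumed to carry an eQTL effect.
#' @return The projected count of spurious secondary associations.
#' @examples
#' projectedSpuriousCount(0.2)
#' @export
projectedSpuriousCount <- function(cumulativeProportion,
                                   nUntyped = 1.9e6,
                                   genicFraction = 0.14,
                                   functionalFraction = 0.001) {
  stopifnot(cumulativeProportion >= 0, cumulativeProportion <= 1)
  cumulativeProportion * nUntyped * genicFraction * functionalFraction
}
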