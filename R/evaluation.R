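# Replicate scoring: credible-set tagging, causal capture, RTC,
# variance decomposition, bias surfaces, and the scenario experiment
# driver with Table-style aggregation.

.peakIdx <- function(pk) {
  if (methods::is(pk, "StepwisePeaks")) pk@peaks$variantIdx else
    as.integer(pk)
}

#' Match discovered peaks to simulated causal variants
#'
#' Each peak (in discovery order) is matched to the causal variant with
#' r-squared above `r2Cut` that has the largest true `|beta|`; a causal
#' already claimed by an earlier peak is unavailable to later ones, so a
#' causal can be claimed by at most one peak. Peaks with no qualifying
#' causal are flagged spurious.
#'
#' @param peaks a [StepwisePeaks-class] (or integer vector of peak column
#'   indices, treated as discovery order).
#' @param config the [CausalConfig-class] truth.
#' @param ld a symmetric panel r-squared matrix indexable by variant column
#'   index (see [ldMatrix()]).
#' @param r2Cut credible-set LD cutoff (default 0.8).
#' @return A list of class `TaggingReport`: `table` (one row per peak:
#'   `peakIdx`, `matchedCausal`, `r2`, `spurious`), `nPeaks`, `nMatched`,
#'   `proportionMatched`.
#' @export
matchPeaksToCausals <- function(peaks, config, ld, r2Cut = 0.8) {
  pidx <- .peakIdx(peaks)
  cidx <- config@causalIdx
  claimed <- logical(length(cidx))
  rows <- lapply(seq_along(pidx), function(i) {
    r2 <- ld[pidx[i], cidx]
    cand <- which(r2 > r2Cut & !claimed)
    if (length(cand)) {
      best <- cand[which.max(abs(config@beta[cand]))]
      claimed[best] <<- TRUE
      data.frame(peakIdx = pidx[i], matchedCausal = cidx[best],
                 r2 = r2[best], spurious = FALSE)
    } else {
      data.frame(peakIdx = pidx[i], matchedCausal = NA_integer_,
                 r2 = if (length(r2)) max(r2) else NA_real_,
                 spurious = TRUE)
    }
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peakIdx = integer(), matchedCausal = integer(),
               r2 = numeric(), spurious = logical())
  structure(list(table = tab, nPeaks = length(pidx),
                 nMatched = sum(!tab$spurious),
                 proportionMatched = if (length(pidx))
                   mean(!tab$spurious) else NA_real_),
            class = "TaggingReport")
}

#' Count causal variants captured by discovered peaks
#'
#' The reciprocal of [matchPeaksToCausals()], with no deduplication: a
#' causal variant is captured if and only if at least one peak has
#' r-squared above `r2Cut` with it (the peak's credible interval contains
#' the causal site). One peak can capture several causals.
#'
#' @inheritParams matchPeaksToCausals
#' @return A list of class `DetectionReport`: `perCausal` (one row per
#'   causal: `causalIdx`, `bestR2`, `captured`) and `nCausalCaptured`.
#' @export
countCapturedCausals <- function(peaks, config, ld, r2Cut = 0.8) {
  pidx <- .peakIdx(peaks)
  cidx <- config@causalIdx
  bestR2 <- if (length(pidx)) {
    apply(ld[pidx, cidx, drop = FALSE], 2L, max)
  } else rep(NA_real_, length(cidx))
  captured <- !is.na(bestR2) & bestR2 > r2Cut
  structure(list(perCausal = data.frame(causalIdx = cidx, bestR2 = bestR2,
                                        captured = captured),
                 nCausalCaptured = sum(captured)),
            class = "DetectionReport")
}

#' Regulatory Trait Concordance (RTC) score
#'
#' `RTC = (N_SNPs - rank) / N_SNPs`, where `rank` is the 0-based position
#' of the causal variant when all variants in the locus are ordered by
#' ascending association p-value. A score of 1 means the causal site is
#' the top-ranked association; tied p-values share the minimal rank. The
#' score is invariant under monotone transformations of the p-values.
#'
#' @param scan a scan data.frame from [univariateScan()] (columns
#'   `variantIdx` and `p`), or a bare numeric p-value vector indexed by
#'   variant column.
#' @param causalIdx the causal variant's column index.
#' @param nSnps locus SNP count; defaults to the number of scanned
#'   variants.
#' @return RTC score in (0, 1\].
#' @examples
#' rtcScore(c(0.5, 1e-8, 0.2), causalIdx = 2)   # causal top-ranked: 1
#' @export
rtcScore <- function(scan, causalIdx, nSnps = NULL) {
  p <- if (is.data.frame(scan)) {
    stats::setNames(scan$p, scan$variantIdx)[as.character(seq_len(max(scan$variantIdx)))]
  } else as.numeric(scan)
  if (causalIdx < 1 || causalIdx > length(p) || is.na(p[causalIdx]))
    stop("causal variant ", causalIdx, " is absent from the ranking universe",
         call. = FALSE)
  if (is.null(nSnps)) nSnps <- sum(!is.na(p))
  rank0 <- sum(p < p[causalIdx], na.rm = TRUE)   # ties share the minimal rank
  (nSnps - rank0) / nSnps
}

#' Decompose trait variance captured by truth and by discoveries
#'
#' Computes four coefficients of determination on one replicate: `simu`
#' (the simulated causal sites fitted jointly), `multi` (the discovered
#' peaks fitted jointly), `uni` (the summed contributions of the
#' sequential conditional steps, i.e. the variance removed by residual
#' forwarding), and `single` (the first-discovered peak alone). With no
#' peaks, the discovered quantities are zero.
#'
#' @param G a [GenotypePanel-class] or dosage matrix.
#' @param y the trait vector of this replicate.
#' @param peaks the replicate's [StepwisePeaks-class].
#' @param config the replicate's [CausalConfig-class].
#' @return A list of class `VarianceDecomposition` with elements
#'   `veSimulated`, `veJoint`, `veConditionalSum`, `veTopPeak`.
#' @export
varianceDecomposition <- function(G, y, peaks, config) {
  X <- if (methods::is(G, "GenotypePanel")) dosages(G) else as.matrix(G)
  veSim <- jointFit(X, y, config@causalIdx)@r2
  pidx <- .peakIdx(peaks)
  if (!length(pidx)) {
    return(structure(list(veSimulated = veSim, veJoint = 0,
                          veConditionalSum = 0, veTopPeak = 0),
                     class = "VarianceDecomposition"))
  }
  veJoint <- jointFit(X, y, pidx)@r2
  # replay residual forwarding to accumulate per-step contributions
  r <- y
  v0 <- sum((y - mean(y))^2)
  for (j in pidx) {
    xc <- X[, j] - mean(X[, j])
    rc <- r - mean(r)
    r <- rc - sum(xc * rc) / sum(xc^2) * xc
  }
  veCond <- 1 - sum((r - mean(r))^2) / v0
  veTop <- jointFit(X, y, pidx[1L])@r2
  structure(list(veSimulated = veSim, veJoint = veJoint,
                 veConditionalSum = veCond, veTopPeak = veTop),
            class = "VarianceDecomposition")
}

#' Bin effect-size estimation errors into a bias surface
#'
#' Aggregates scored (peak, causal) pairs — discovered peaks matched to a
#' causal variant at the credible-set cutoff — into 2-D bins over the true
#' effect magnitude `|beta|` (sdu) and the causal site's mean r-squared
#' with its co-causal sites. Cell values are the mean absolute deviation
#' `|beta_hat - beta|` for the conditional and for the joint estimates; the
#' difference layer is joint minus conditional, so negative cells mean the
#' multisite model is closer to the truth. Empty cells are `NA`, not zero.
#'
#' @param scored data.frame with columns `trueBeta` (signed, sdu),
#'   `meanR2`, `devCond`, `devJoint` — e.g. the `scored` element of
#'   [runExperiment()].
#' @param betaBin,r2Bin bin widths (defaults 0.1 sdu and 0.05).
#' @return A list of class `BiasSurface`: matrices `conditional`, `joint`,
#'   `difference`, `counts`, and the bin edges.
#' @export
biasSurface <- function(scored, betaBin = 0.1, r2Bin = 0.05) {
  stopifnot(nrow(scored) >= 1L,
            all(c("trueBeta", "meanR2", "devCond", "devJoint") %in%
                  names(scored)))
  ab <- abs(scored$trueBeta)
  betaBreaks <- seq(0, ceiling(max(ab) / betaBin) * betaBin, by = betaBin)
  r2Breaks <- seq(0, 1, by = r2Bin)
  bi <- cut(ab, betaBreaks, include.lowest = TRUE)
  ri <- cut(pmin(scored$meanR2, 1), r2Breaks, include.lowest = TRUE)
  agg <- function(v) tapply(v, list(bi, ri), mean, na.rm = TRUE)
  counts <- table(bi, ri)
  cond <- agg(scored$devCond)
  joint <- agg(scored$devJoint)
  structure(list(conditional = cond, joint = joint,
                 difference = joint - cond,
                 counts = unclass(counts),
                 betaBreaks = betaBreaks, r2Breaks = r2Breaks),
            class = "BiasSurface")
}

# Counter-based replicate seed stream: the k-th sub-seed depends only on
# the master seed and k, never on the total replicate count.
.repSeeds <- function(seed, reps) {
  .setSeed(seed)
  sample.int(2147483646L, reps)
}

#' Run a multi-causal detection/estimation experiment
#'
#' The full pipeline of the scenario study, per replicate: simulate a
#' block-LD locus panel, draw `k` causal sites, assign signed effects
#' under the scenario, simulate the trait, run sequential conditional
#' detection, refit discovered peaks jointly, and score tagging, capture,
#' variance decomposition, RTC of the primary signal against the
#' largest-effect causal, and per-match effect-size deviations.
#'
#' @param reps number of replicates.
#' @param nSamples,nSnps panel dimensions per replicate (defaults: 1839
#'   samples, 100 variants).
#' @param k number of causal sites.
#' @param scenario sign scenario (`"4:0"`, `"3:1"`, `"2:2"`, ... with
#'   counts summing to `k`).
#' @param veRange uniform VE range, default (0.02, 0.10).
#' @param alpha stepwise significance threshold, default `1e-5`.
#' @param r2Cut credible-set cutoff, default 0.8.
#' @param maxSteps stepwise step cap.
#' @param blockSpec,mafSpec panel generation controls (see
#'   [simulateLocus()]); defaults give two large and one small high-LD
#'   block and uniform maf on (0.01, 0.5).
#' @param seed master seed; replicates use a counter-based sub-seed
#'   stream, so replicate k's results do not depend on `reps`.
#' @return A list of class `ExperimentResult`: `replicates` (one row per
#'   replicate: peak/match/capture counts, variance decomposition, RTC),
#'   `scored` (per matched peak-causal pair, input to [biasSurface()]),
#'   `table1` (detection-count distribution with tagging proportions),
#'   `table2` (captured-count distribution), and `settings`.
#' @examples
#' res <- runExperiment(reps = 3, nSamples = 300, nSnps = 40, seed = 1)
#' res$replicates
#' @export
runExperiment <- function(reps, nSamples = 1839L, nSnps = 100L, k = 4L,
                          scenario = "4:0", veRange = c(0.02, 0.10),
                          alpha = 1e-5, r2Cut = 0.8, maxSteps = 10L,
                          blockSpec = NULL, mafSpec = NULL, seed = NULL) {
  stopifnot(reps >= 1L)
  seeds <- .repSeeds(seed, reps)
  repRows <- vector("list", reps)
  scoredRows <- vector("list", reps)
  counts <- as.integer(strsplit(scenario, ":", fixed = TRUE)[[1L]])
  if (length(counts) != 2L || anyNA(counts) || sum(counts) != k)
    stop("scenario '", scenario, "' sign counts must sum to ", k,
         call. = FALSE)
  for (i in seq_len(reps)) {
    set.seed(seeds[i])
    X <- .simulateLocusRaw(nSamples, nSnps, blockSpec, mafSpec)$dosages
    pbar <- colMeans(X) / 2
    maf <- pmin(pbar, 1 - pbar)
    cidx <- sort(sample.int(nSnps, k))
    cfg <- .assignEffectsFromMaf(maf[cidx], cidx, veRange, counts, scenario)
    y <- as.vector(X[, cidx, drop = FALSE] %*% (cfg@sign * cfg@beta)) +
      rnorm(nSamples)
    sw <- stepwiseConditional(X, y, alpha = alpha, maxSteps = maxSteps)
    scan <- univariateScan(X, y)
    ld <- cor(X)^2
    tag <- matchPeaksToCausals(sw, cfg, ld, r2Cut = r2Cut)
    det <- countCapturedCausals(sw, cfg, ld, r2Cut = r2Cut)
    vd <- varianceDecomposition(X, y, sw, cfg)
    topCausal <- cfg@causalIdx[which.max(cfg@beta)]
    rtc <- if (nrow(sw@peaks)) rtcScore(scan, topCausal) else NA_real_
    jf <- if (nrow(sw@peaks)) jointFit(X, y, sw@peaks$variantIdx) else NULL
    sc <- tag$table[!tag$table$spurious, , drop = FALSE]
    if (nrow(sc)) {
      ci <- match(sc$matchedCausal, cfg@causalIdx)
      meanR2 <- vapply(sc$matchedCausal, function(cc) {
        others <- setdiff(cfg@causalIdx, cc)
        if (length(others)) mean(ld[cc, others]) else 0
      }, numeric(1))
      jb <- jf@beta[match(sc$peakIdx, jf@idx)]
      cb <- sw@peaks$beta[match(sc$peakIdx, sw@peaks$variantIdx)]
      truth <- cfg@sign[ci] * cfg@beta[ci]
      scoredRows[[i]] <- data.frame(
        rep = i, peakIdx = sc$peakIdx, causalIdx = sc$matchedCausal,
        trueBeta = truth, meanR2 = meanR2,
        devCond = abs(cb - truth), devJoint = abs(jb - truth))
    }
    repRows[[i]] <- data.frame(
      rep = i, seed = seeds[i], nPeaks = nrow(sw@peaks),
      nMatched = tag$nMatched,
      propMatched = tag$proportionMatched,
      nCaptured = det$nCausalCaptured,
      veSimulated = vd$veSimulated, veJoint = vd$veJoint,
      veConditionalSum = vd$veConditionalSum, veTopPeak = vd$veTopPeak,
      rtc = rtc)
  }
  replicates <- do.call(rbind, repRows)
  scored <- do.call(rbind, scoredRows)
  structure(list(replicates = replicates, scored = scored,
                 table1 = .detectionTable(replicates, k),
                 table2 = .captureTable(replicates, k),
                 settings = list(reps = reps, nSamples = nSamples,
                                 nSnps = nSnps, k = k, scenario = scenario,
                                 veRange = veRange, alpha = alpha,
                                 r2Cut = r2Cut, seed = seed)),
            class = "ExperimentResult")
}

# Detection-count distribution with mean tagging proportion in brackets
# (rows 0, 1, ..., k, >k; percentages sum to 100 over rows).
.detectionTable <- function(replicates, k) {
  lev <- c(as.character(0:k), paste0(">", k))
  np <- ifelse(replicates$nPeaks > k, paste0(">", k),
               as.character(replicates$nPeaks))
  np <- factor(np, levels = lev)
  pct <- 100 * as.vector(table(np)) / nrow(replicates)
  prop <- tapply(replicates$propMatched, np, mean, na.rm = TRUE)
  data.frame(detected = lev, percent = pct,
             proportionTagged = as.vector(prop))
}

.captureTable <- function(replicates, k) {
  nc <- factor(replicates$nCaptured, levels = 0:k)
  data.frame(capturedTrue = 0:k,
             percent = 100 * as.vector(table(nc)) / nrow(replicates))
}
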