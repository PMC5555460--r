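# Association machinery: univariate scanning, sequential conditional
# (stepwise) detection, joint multivariable estimation, the closed-form
# omitted-variable bias, and power / sample-size calculators.

# Vectorized simple-regression scan of y on each column of X.
# Returns beta, se, p (two-sided, exact t with the given df); constant
# columns come back NA. Sxx may be precomputed for repeated scans.
.fastScan <- function(X, y, df = nrow(X) - 2L, xm = NULL, Sxx = NULL) {
  n <- nrow(X)
  if (is.null(xm)) xm <- colMeans(X)
  if (is.null(Sxx)) Sxx <- colSums(X^2) - n * xm^2
  yc <- y - mean(y)
  Syy <- sum(yc^2)
  Sxy <- as.vector(crossprod(X, yc))
  ok <- Sxx > 0
  beta <- se <- p <- rep(NA_real_, ncol(X))
  beta[ok] <- Sxy[ok] / Sxx[ok]
  rss <- pmax(Syy - beta[ok] * Sxy[ok], 0)
  sigma2 <- rss / df
  se[ok] <- sqrt(sigma2 / Sxx[ok])
  tstat <- ifelse(se[ok] > 0, beta[ok] / se[ok], Inf)
  p[ok] <- pmax(2 * pt(-abs(tstat), df), .Machine$double.xmin)
  list(beta = beta, se = se, p = p, ok = ok)
}

#' Univariate association scan
#'
#' Regresses the trait on each variant's minor-allele dosage separately
#' (simple linear regression with intercept), vectorized over variants.
#' P-values come from the exact two-sided t test and are floored at the
#' smallest positive double so a perfect fit never reports zero.
#'
#' @param G a [GenotypePanel-class] or samples-by-variants dosage matrix.
#' @param y numeric trait vector, one value per sample.
#' @return A data.frame with one row per variant: `variantIdx`,
#'   `variantId`, `beta` (sdu per minor allele), `se`, `p`, and `excluded`
#'   (TRUE for constant variants, which get NA estimates).
#' @examples
#' g <- simulateLocus(300, 40, seed = 1)
#' cfg <- assignEffects(g, 10, veRange = c(0.1, 0.1), scenario = "1:0")
#' head(univariateScan(g, simulateTrait(g, cfg, seed = 2)))
#' @export
univariateScan <- function(G, y) {
  X <- if (methods::is(G, "GenotypePanel")) dosages(G) else as.matrix(G)
  stopifnot(length(y) == nrow(X))
  s <- .fastScan(X, y)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(X)))
  data.frame(variantIdx = seq_len(ncol(X)), variantId = ids,
             beta = s$beta, se = s$se, p = s$p, excluded = !s$ok)
}

#' Sequential conditional (stepwise) eQTL detection
#'
#' Repeatedly scans the current working trait; if the smallest p-value is
#' below `alpha`, the best variant is recorded as a peak with its
#' conditional estimate, and the trait is replaced by the residuals of the
#' regression on that variant (residual-forwarding, the field's
#' conventional scheme and the default). In `mode = "covariate"` each scan instead adjusts for all prior
#' peaks as covariates in the model (partial regression); the two differ
#' slightly when peaks are correlated. Ties at identical p-values break to
#' the lowest variant index.
#'
#' @param G a [GenotypePanel-class] or samples-by-variants dosage matrix.
#' @param y numeric trait vector.
#' @param alpha conditional significance threshold (default `1e-5`).
#' @param maxSteps cap on discovery steps (default 10).
#' @param mode `"residual"` (forward residuals; default) or `"covariate"`.
#' @return A [StepwisePeaks-class]; an empty peak table is a valid outcome.
#' @examples
#' g <- simulateLocus(500, 40, seed = 1)
#' cfg <- assignEffects(g, c(5, 30), veRange = c(0.1, 0.1), scenario = "2:0")
#' stepwiseConditional(g, simulateTrait(g, cfg, seed = 2))
#' @export
stepwiseConditional <- function(G, y, alpha = 1e-5, maxSteps = 10L,
                                mode = c("residual", "covariate")) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, maxSteps >= 1L)
  X <- if (methods::is(G, "GenotypePanel")) dosages(G) else as.matrix(G)
  stopifnot(length(y) == nrow(X))
  n <- nrow(X)
  m <- ncol(X)
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("snp", seq_len(m))
  xm <- colMeans(X)
  Sxx0 <- colSums(X^2) - n * xm^2
  work <- y
  Xw <- X
  xmw <- xm
  Sxxw <- Sxx0
  taken <- logical(m)
  rows <- vector("list", 0L)
  stopReason <- "max_steps"
  for (step in seq_len(maxSteps)) {
    df <- if (mode == "residual") n - 2L else n - 2L - (step - 1L)
    s <- .fastScan(Xw, work, df = df, xm = xmw, Sxx = Sxxw)
    pv <- s$p
    pv[taken] <- NA_real_
    if (all(is.na(pv))) { stopReason <- "below_threshold"; break }
    pmin_ <- min(pv, na.rm = TRUE)
    if (pmin_ >= alpha) { stopReason <- "below_threshold"; break }
    best <- min(which(pv == pmin_))
    rows[[length(rows) + 1L]] <- data.frame(
      variantIdx = best, variantId = ids[best], beta = s$beta[best],
      se = s$se[best], p = pmin_, step = step)
    taken[best] <- TRUE
    # forward the residual of the working trait on the discovered variant
    xc <- X[, best] - xm[best]
    wc <- work - mean(work)
    b <- sum(xc * wc) / sum(xc^2)
    work <- wc - b * xc
    if (mode == "covariate") {
      # residualize the panel on the discovered variant as well, so the
      # next scan's estimates are full-model partial coefficients
      Xc <- sweep(Xw, 2L, xmw, "-")
      xcw <- Xc[, best]
      g <- as.vector(crossprod(Xc, xcw)) / sum(xcw^2)
      Xw <- Xc - outer(xcw, g)
      xmw <- rep(0, m)
      Sxxw <- colSums(Xw^2)
      work <- wc - sum(xcw * wc) / sum(xcw^2) * xcw
    }
  }
  pk <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variantIdx = integer(), variantId = character(),
               beta = numeric(), se = numeric(), p = numeric(),
               step = integer())
  methods::new("StepwisePeaks", peaks = pk, stopReason = stopReason,
               alpha = alpha, mode = mode)
}

#' Joint multivariable fit of a set of variants
#'
#' Fits all listed variants simultaneously in one least-squares model with
#' intercept (the "multisite model"). Variants perfectly collinear
#' (pairwise dosage r-squared above `1 - 1e-12`) with an earlier-listed
#' variant are pruned before fitting and reported in the `pruned` slot;
#' remaining rank deficiency, or too few samples (`n <= k + 1`), is an
#' error rather than a silent pseudo-inverse.
#'
#' @param G a [GenotypePanel-class] or samples-by-variants dosage matrix.
#' @param y numeric trait vector.
#' @param idx variant column indices to fit (non-empty).
#' @return A [JointFit-class].
#' @examples
#' g <- samplePair(1000, 0.3, 0.3, sqrt(0.5), seed = 1)
#' cfg <- assignEffects(g, c(1, 2), veRange = c(0.05, 0.05), scenario = "2:0")
#' jointFit(g, simulateTrait(g, cfg, seed = 2), c(1, 2))
#' @export
jointFit <- function(G, y, idx) {
  X <- if (methods::is(G, "GenotypePanel")) dosages(G) else as.matrix(G)
  idx <- as.integer(idx)
  stopifnot(length(idx) >= 1L, all(idx >= 1L), all(idx <= ncol(X)),
            !anyDuplicated(idx), length(y) == nrow(X))
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(X)))
  keep <- idx
  pruned <- integer()
  if (length(idx) > 1L) {
    r2 <- suppressWarnings(cor(X[, idx, drop = FALSE])^2)
    drop <- rep(FALSE, length(idx))
    for (j in 2:length(idx)) {
      if (any(r2[j, seq_len(j - 1L)][!drop[seq_len(j - 1L)]] > 1 - 1e-12,
              na.rm = TRUE))
        drop[j] <- TRUE
    }
    pruned <- idx[drop]
    keep <- idx[!drop]
  }
  k <- length(keep)
  if (nrow(X) <= k + 1L)
    stop("n = ", nrow(X), " samples cannot identify ", k,
         " coefficients plus an intercept", call. = FALSE)
  M <- cbind(1, X[, keep, drop = FALSE])
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    badcols <- qrM$pivot[(qrM$rank + 1L):ncol(M)]
    bad <- keep[badcols[badcols > 1L] - 1L]
    stop("design is rank-deficient after pruning; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- qr.coef(qrM, y)
  res <- y - M %*% cf
  dfres <- nrow(X) - ncol(M)
  sigma2 <- sum(res^2) / dfres
  Rinv <- chol2inv(qr.R(qrM))
  XtXinv <- matrix(0, ncol(M), ncol(M))
  XtXinv[qrM$pivot, qrM$pivot] <- Rinv
  V <- sigma2 * XtXinv[-1L, -1L, drop = FALSE]
  yc <- y - mean(y)
  r2model <- 1 - sum(res^2) / sum(yc^2)
  methods::new("JointFit", idx = keep, variantId = ids[keep],
               beta = unname(cf[-1L]), se = sqrt(diag(V)),
               vcov = V, r2 = max(0, min(1, r2model)), pruned = pruned)
}

#' Expected omitted-variable bias of a univariate effect estimate
#'
#' When two causal variants are in LD and only the focal one is fitted, its
#' univariate estimate is shifted by the omitted site. The expectation is
#' `E(beta1_hat) - beta1 = r beta2 sqrt(p2 (1 - p2) / (p1 (1 - p1)))`,
#' i.e. the omitted effect scaled by `Cov(g1, g2) / Var(g1)` written in
#' terms of the signed dosage correlation `r` and the two minor allele
#' frequencies. The frequency-ratio orientation was fixed against a
#' large-sample simulation oracle; the bias is maximized for
#' frequency-matched pairs, where it reduces to `r * beta2`.
#'
#' @param r signed dosage correlation between the two variants; must
#'   satisfy `abs(r) <= maxAbsR(pFocal, pOther)`.
#' @param betaOther signed effect (sdu) of the omitted causal variant.
#' @param pFocal,pOther minor allele frequencies in (0, 0.5].
#' @return Expected bias of the focal univariate estimate, in sdu.
#' @examples
#' expectedUnivariateBias(0, 0.5, 0.2, 0.2)       # no LD, no confounding
#' expectedUnivariateBias(0.5, 0.4, 0.3, 0.3)     # r * beta2 when p1 = p2
#' @export
expectedUnivariateBias <- function(r, betaOther, pFocal, pOther) {
  .checkMaf(c(pFocal, pOther))
  if (abs(r) > maxAbsR(pFocal, pOther) + 1e-12)
    stop("|r| exceeds the attainable bound ",
         signif(maxAbsR(pFocal, pOther), 6), " for these frequencies",
         call. = FALSE)
  r * betaOther * sqrt(pOther * (1 - pOther) / (pFocal * (1 - pFocal)))
}

#' Power of the univariate association test
#'
#' Closed-form power of the single-variant regression test from the
#' noncentral F distribution with 1 and `n - 2` degrees of freedom. With VE
#' defined relative to unit environmental noise, the noncentrality is
#' `lambda = n * ve` (residual variance equals the unit noise).
#'
#' @param ve variance explained by the variant, relative to unit noise
#'   (`ve = 0` returns `alpha`).
#' @param n sample size (at least 3).
#' @param alpha significance threshold.
#' @return Power in \[0, 1\]; monotone increasing in `ve` and `n`.
#' @examples
#' univariatePower(0.05, 1839, 1e-5)   # essentially 1
#' @export
univariatePower <- function(ve, n, alpha = 1e-5) {
  stopifnot(ve >= 0, n >= 3, alpha > 0, alpha < 1)
  crit <- qf(1 - alpha, 1, n - 2)
  1 - pf(crit, 1, n - 2, ncp = n * ve)
}

#' Sample size needed for accurate joint estimation of a linked pair
#'
#' For a pair of causal variants with LD `r2`, each explaining `veEach` of
#' variance (same effect direction, equal minor allele frequencies), this
#' simulates genotype pairs, fits both variants jointly, and measures the
#' estimation error `|beta_hat - beta|` averaged over both sites, at every
#' sample size in `nGrid`. It returns the smallest n whose error statistic
#' meets `tol`, together with the full error-vs-n curve. Mean absolute
#' error is the headline criterion; root-mean-square error and the
#' estimator SD are reported alongside.
#'
#' Generation and fitting are vectorized over replicates but use exactly
#' the two-locus haplotype model of [samplePair()] and the closed-form
#' least squares of [jointFit()].
#'
#' @param r2 LD target (dosage r-squared) between the pair.
#' @param veEach per-site variance explained relative to unit noise.
#' @param tol error tolerance in sdu (default 0.1).
#' @param nGrid ascending grid of sample sizes.
#' @param reps simulation replicates per grid point (at least 100).
#' @param maf shared minor allele frequency; the default makes
#'   `2 p (1 - p) = 0.4`, so `veEach = 0.1` corresponds to 0.5 sdu effects.
#' @param criterion which error statistic the tolerance applies to.
#' @param seed optional integer seed.
#' @return A list with `requiredN` (smallest qualifying n, or `NA` with
#'   `reached = FALSE` if the criterion is never met on the grid), the
#'   `curve` data.frame (`n`, `mae`, `rmse`, `sd`), and the settings.
#' @examples
#' rs <- requiredSampleSize(0.9, 0.1, nGrid = seq(200, 1000, 200),
#'                          reps = 200, seed = 1)
#' rs$curve
#' @export
requiredSampleSize <- function(r2, veEach, tol = 0.1,
                               nGrid = seq(100L, 3000L, by = 100L),
                               reps = 1000L,
                               maf = (1 - sqrt(1 - 0.8)) / 2,
                               criterion = c("mae", "rmse", "sd"),
                               seed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(r2 >= 0, r2 < 1, veEach > 0, veEach < 1, reps >= 100L,
            all(diff(nGrid) > 0))
  .checkMaf(maf)
  r <- sqrt(r2)
  beta <- betaFromVe(veEach, maf)
  .setSeed(seed)
  curve <- data.frame(n = as.integer(nGrid), mae = NA_real_,
                      rmse = NA_real_, sd = NA_real_)
  for (i in seq_along(nGrid)) {
    n <- nGrid[i]
    chunk <- max(1L, min(reps, floor(2e6 / n)))
    errs <- numeric(0)
    done <- 0L
    while (done < reps) {
      b <- min(chunk, reps - done)
      d <- .samplePairDosages(n, b, maf, maf, r)
      noise <- matrix(rnorm(n * b), nrow = n)
      Y <- beta * (d$x1 + d$x2) + noise
      est <- .jointFitPairBatch(d$x1, d$x2, Y)
      errs <- c(errs, est$b1 - beta, est$b2 - beta)
      done <- done + b
    }
    errs <- errs[is.finite(errs)]
    curve$mae[i] <- mean(abs(errs))
    curve$rmse[i] <- sqrt(mean(errs^2))
    curve$sd[i] <- sd(errs)
  }
  met <- which(curve[[criterion]] <= tol)
  list(requiredN = if (length(met)) curve$n[min(met)] else NA_integer_,
       reached = length(met) > 0, curve = curve, criterion = criterion,
       tol = tol, r2 = r2, veEach = veEach, maf = maf, reps = reps)
}

# Closed-form two-predictor OLS, vectorized across replicate columns of
# x1, x2, Y (all n x reps). Returns per-replicate coefficient vectors.
.jointFitPairBatch <- function(x1, x2, Y) {
  n <- nrow(Y)
  m1 <- colMeans(x1); m2 <- colMeans(x2); my <- colMeans(Y)
  S11 <- colSums(x1^2) - n * m1^2
  S22 <- colSums(x2^2) - n * m2^2
  S12 <- colSums(x1 * x2) - n * m1 * m2
  S1y <- colSums(x1 * Y) - n * m1 * my
  S2y <- colSums(x2 * Y) - n * m2 * my
  det <- S11 * S22 - S12^2
  det[det <= 0] <- NA_real_
  list(b1 = (S22 * S1y - S12 * S2y) / det,
       b2 = (S11 * S2y - S12 * S1y) / det)
}
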