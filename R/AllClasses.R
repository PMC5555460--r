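#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames rowData colData
#' @importFrom stats cor qnorm pnorm rnorm runif rbinom pt pf qf var sd quantile
#'   complete.cases setNames lm coef vcov resid pbeta
#' @importFrom utils read.delim write.table head modifyList
NULL

#' GenotypePanel: diploid dosage genotypes with variant metadata
#'
#' An S4 container for an n-sample by m-variant panel of minor-allele dosage
#' genotypes (values in \[0, 2\]; generated panels are integer 0/1/2, file
#' input may carry fractional imputed dosages). It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single `"dosage"`
#' assay stored variants-by-samples, and `rowData` columns `position`
#' (base pairs along the simulated locus) and `maf` (empirical minor allele
#' frequency in (0, 0.5]).
#'
#' Construct panels with [GenotypePanel()], [samplePair()], [simulateLocus()]
#' or [readGenotypes()]; extract the regression-oriented n x m dosage matrix
#' with [dosages()].
#'
#' @aliases GenotypePanel-class
#' @seealso [dosages()], [mafs()], [variantPositions()], [ldMatrix()]
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'dosage' is missing")
  d <- SummarizedExperiment::assay(object, "dosage")
  if (!is.numeric(d))
    return("dosage assay must be numeric")
  if (any(!is.finite(d)) || any(d < 0) || any(d > 2))
    return("dosages must be finite values in [0, 2]")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("position", "maf") %in% colnames(rd)))
    return("rowData must contain 'position' and 'maf'")
  pos <- rd$position
  if (nrow(d) > 1L && any(diff(pos) <= 0))
    return("positions must be strictly increasing")
  maf <- rd$maf
  if (any(maf <= 0) || any(maf > 0.5))
    return("maf must lie in (0, 0.5]")
  emp <- pmin(rowMeans(d) / 2, 1 - rowMeans(d) / 2)
  if (any(abs(emp - maf) > 1e-6))
    return("maf metadata disagrees with dosage column means")
  TRUE
})

#' Construct a GenotypePanel from a dosage matrix
#'
#' @param dosages numeric matrix, samples in rows and variants in columns,
#'   minor-allele dosages in \[0, 2\].
#' @param positions integer/numeric base-pair coordinates, one per variant,
#'   strictly increasing. Defaults to `1:m`.
#' @param variantIds character labels, one per variant.
#' @param sampleIds character labels, one per sample.
#' @return A [GenotypePanel-class] object.
#' @examples
#' g <- GenotypePanel(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' mafs(g)
#' @export
GenotypePanel <- function(dosages, positions = NULL, variantIds = NULL,
                          sampleIds = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  n <- nrow(dosages)
  if (is.null(positions)) positions <- seq_len(m)
  if (is.null(variantIds)) variantIds <- paste0("snp", seq_len(m))
  if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(n))
  stopifnot(length(positions) == m, length(variantIds) == m,
            length(sampleIds) == n)
  ord <- order(positions)
  dimnames(dosages) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  positions <- positions[ord]
  variantIds <- variantIds[ord]
  p <- colMeans(dosages) / 2
  maf <- pmin(p, 1 - p)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = t(dosages)),
    rowData = S4Vectors::DataFrame(position = positions, maf = maf,
                                   row.names = variantIds),
    colData = S4Vectors::DataFrame(row.names = sampleIds))
  methods::new("GenotypePanel", se)
}

#' CausalConfig: the simulated truth for one replicate
#'
#' Holds the causal variant indices, per-site variance explained (VE,
#' relative to unit environmental noise), effect signs, and effect sizes
#' `beta` in trait standard-deviation units (sdu), together with the sign
#' scenario label (e.g. `"4:0"`, `"3:1"`, `"2:2"`). The invariant
#' `beta = sqrt(ve / (2 p (1 - p)))` ties each site's unsigned effect to its
#' minor allele frequency `p`.
#'
#' @aliases CausalConfig-class
#' @seealso [assignEffects()], [simulateTrait()]
#' @export
setClass("CausalConfig",
         representation(causalIdx = "integer", ve = "numeric",
                        sign = "numeric", beta = "numeric", maf = "numeric",
                        scenario = "character"))

setValidity("CausalConfig", function(object) {
  k <- length(object@causalIdx)
  if (length(object@ve) != k || length(object@sign) != k ||
      length(object@beta) != k || length(object@maf) != k)
    return("causalIdx, ve, sign, beta and maf must have equal length")
  if (anyDuplicated(object@causalIdx))
    return("causal indices must be distinct")
  if (any(!object@sign %in% c(-1, 1)))
    return("signs must be +1 or -1")
  if (any(object@ve <= 0) || any(object@ve >= 1))
    return("ve must lie in (0, 1)")
  if (any(abs(object@beta - sqrt(object@ve / (2 * object@maf * (1 - object@maf)))) > 1e-8))
    return("beta must equal sqrt(ve / (2 p (1 - p)))")
  sc <- object@scenario
  if (length(sc) == 1L && grepl("^[0-9]+:[0-9]+$", sc)) {
    counts <- as.integer(strsplit(sc, ":", fixed = TRUE)[[1L]])
    if (sum(counts) != k)
      return("scenario sign counts must sum to the number of causal sites")
    if (sum(object@sign == 1) != counts[1L] || sum(object@sign == -1) != counts[2L])
      return("scenario label disagrees with the sign vector")
  }
  TRUE
})

#' StepwisePeaks: ordered stepwise-conditional discoveries
#'
#' Result of [stepwiseConditional()]: one row per discovered peak, in
#' discovery order, carrying the conditional effect estimate and p-value at
#' the step where the peak was found, plus the stop reason
#' (`"below_threshold"` or `"max_steps"`).
#'
#' @aliases StepwisePeaks-class
#' @seealso [stepwiseConditional()], [peaks()]
#' @export
setClass("StepwisePeaks",
         representation(peaks = "data.frame", stopReason = "character",
                        alpha = "numeric", mode = "character"))

setValidity("StepwisePeaks", function(object) {
  pk <- object@peaks
  need <- c("variantIdx", "variantId", "beta", "se", "p", "step")
  if (!all(need %in% names(pk)))
    return(paste("peaks must have columns", paste(need, collapse = ", ")))
  if (nrow(pk)) {
    if (any(diff(pk$step) <= 0)) return("steps must be strictly increasing")
    if (any(pk$p >= object@alpha)) return("retained peaks must have p < alpha")
    if (anyDuplicated(pk$variantIdx)) return("peak variants must be distinct")
  }
  TRUE
})

#' JointFit: multivariable least-squares fit of selected variants
#'
#' Result of [jointFit()]: joint effect estimates (sdu per minor allele) for
#' a set of variants fitted simultaneously with an intercept, their
#' standard errors and covariance, the model coefficient of determination
#' (`r2`, the fraction of trait variance explained by the fitted set), and
#' the indices pruned as perfectly collinear before fitting.
#'
#' @aliases JointFit-class
#' @seealso [jointFit()]
#' @export
setClass("JointFit",
         representation(idx = "integer", variantId = "character",
                        beta = "numeric", se = "numeric", vcov = "matrix",
                        r2 = "numeric", pruned = "integer"))

setValidity("JointFit", function(object) {
  if (anyDuplicated(object@idx)) return("indices must be distinct")
  if (length(object@beta) != length(object@idx))
    return("beta and idx lengths differ")
  if (object@r2 < 0 || object@r2 > 1) return("r2 must lie in [0, 1]")
  TRUE
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", ncol(object), "samples x", nrow(object), "variants\n")
  cat("  maf range: [", sprintf("%.3f", min(mafs(object))), ", ",
      sprintf("%.3f", max(mafs(object))), "]\n", sep = "")
  cat("  positions: ", min(variantPositions(object)), "-",
      max(variantPositions(object)), " bp\n", sep = "")
})

setMethod("show", "CausalConfig", function(object) {
  cat("CausalConfig (scenario ", object@scenario, "): ",
      length(object@causalIdx), " causal sites\n", sep = "")
  print(data.frame(idx = object@causalIdx, maf = round(object@maf, 3),
                   ve = round(object@ve, 4),
                   beta = round(object@sign * object@beta, 4)))
})

setMethod("show", "StepwisePeaks", function(object) {
  cat("StepwisePeaks: ", nrow(object@peaks), " peak(s), alpha = ",
      format(object@alpha), ", mode = ", object@mode,
      ", stop: ", object@stopReason, "\n", sep = "")
  if (nrow(object@peaks)) print(object@peaks, row.names = FALSE)
})

setMethod("show", "JointFit", function(object) {
  cat("JointFit:", length(object@idx), "variant(s), R^2 =",
      sprintf("%.4f", object@r2), "\n")
  print(data.frame(idx = object@idx, beta = round(object@beta, 4),
                   se = round(object@se, 4)))
  if (length(object@pruned))
    cat("  pruned (collinear):", paste(object@pruned, collapse = ", "), "\n")
})
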