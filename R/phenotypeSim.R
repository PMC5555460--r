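# Trait simulation: additive minor-allele effects in sdu over unit
# environmental noise, parameterized by per-site variance explained.

#' Convert between variance explained and allelic effect size
#'
#' For an additive variant with minor allele frequency `p`, an effect of
#' `beta` trait standard-deviation units (sdu) per minor allele explains
#' `ve = 2 p (1 - p) beta^2` of variance (relative to unit environmental
#' noise); conversely `beta = sqrt(ve / (2 p (1 - p)))`. For example
#' `beta = 0.8` explains 20% of variance at maf 0.2 and 32% at maf 0.5.
#'
#' @param ve variance explained, in (0, 1) (relative to unit noise).
#' @param beta unsigned allelic effect in sdu.
#' @param p minor allele frequency in (0, 0.5].
#' @return `betaFromVe()`: the positive effect size in sdu (signs are
#'   assigned separately); `veFromBeta()`: the variance explained.
#' @examples
#' veFromBeta(0.8, 0.2)   # 0.2048
#' veFromBeta(0.8, 0.5)   # 0.32
#' betaFromVe(0.1, 0.2764)  # ~0.5 sdu (2 p (1 - p) ~ 0.4)
#' @export
betaFromVe <- function(ve, p) {
  .checkMaf(p)
  if (any(!is.finite(ve)) || any(ve <= 0) || any(ve >= 1))
    stop("ve must lie in (0, 1)", call. = FALSE)
  sqrt(ve / (2 * p * (1 - p)))
}

#' @rdname betaFromVe
#' @export
veFromBeta <- function(beta, p) {
  .checkMaf(p)
  2 * p * (1 - p) * beta^2
}

#' Assign causal effect sizes under a sign scenario
#'
#' Each causal site receives a variance explained drawn from
#' `Uniform(veRange)` (or a fixed per-site value via `veFixed`), a sign
#' according to the scenario label (`"a:b"` = `a` positive and `b` negative
#' minor-allele effects; which sites are negative is chosen uniformly at
#' random), and the implied `beta = sqrt(ve / (2 p (1 - p)))`.
#'
#' @param G a [GenotypePanel-class].
#' @param causalIdx variant column indices of the causal sites.
#' @param veRange length-2 range for Uniform VE draws; the default
#'   (0.02, 0.10) spans typical cis-eQTL effect sizes.
#' @param scenario sign scenario label such as `"4:0"`, `"3:1"`, `"2:2"`.
#' @param veFixed optional fixed VE value(s), recycled across sites,
#'   overriding `veRange` (e.g. a grid of 0.02-0.30).
#' @param seed optional integer seed.
#' @return A [CausalConfig-class].
#' @examples
#' g <- simulateLocus(200, 50, seed = 1)
#' assignEffects(g, c(3, 10, 21, 40), scenario = "3:1", seed = 2)
#' @export
assignEffects <- function(G, causalIdx, veRange = c(0.02, 0.10),
                          scenario = "4:0", veFixed = NULL, seed = NULL) {
  causalIdx <- as.integer(causalIdx)
  k <- length(causalIdx)
  stopifnot(k >= 1L, all(causalIdx >= 1L), all(causalIdx <= nVariants(G)))
  counts <- as.integer(strsplit(scenario, ":", fixed = TRUE)[[1L]])
  if (length(counts) != 2L || anyNA(counts) || sum(counts) != k)
    stop("scenario '", scenario, "' sign counts must sum to ", k,
         " causal sites", call. = FALSE)
  .setSeed(seed)
  p <- unname(mafs(G)[causalIdx])
  .assignEffectsFromMaf(p, causalIdx, veRange, counts, scenario, veFixed)
}

# Effect assignment from a maf vector (no panel access); uses the current
# RNG stream.
.assignEffectsFromMaf <- function(p, causalIdx, veRange, counts, scenario,
                                  veFixed = NULL) {
  k <- length(causalIdx)
  ve <- if (is.null(veFixed)) {
    runif(k, veRange[1L], veRange[2L])
  } else rep_len(veFixed, k)
  sgn <- rep(1, k)
  if (counts[2L] > 0) sgn[sample.int(k, counts[2L])] <- -1
  methods::new("CausalConfig", causalIdx = as.integer(causalIdx), ve = ve,
               sign = sgn, beta = betaFromVe(ve, p), maf = p,
               scenario = scenario)
}

#' Simulate an expression trait from a causal configuration
#'
#' The trait is `y = sum_i sign_i beta_i dosage_i + N(0, 1)`: additive
#' minor-allele effects in sdu on top of standard normal environmental
#' noise. The genetic component is computed from raw dosages (centering is
#' absorbed by regression intercepts downstream); the trait is not
#' re-standardized after adding genetic effects.
#'
#' @param G a [GenotypePanel-class].
#' @param config a [CausalConfig-class].
#' @param seed optional integer seed.
#' @return Numeric trait vector of length `nSamples(G)`, with the seed
#'   recorded in attribute `"seed"`.
#' @examples
#' g <- simulateLocus(200, 50, seed = 1)
#' cfg <- assignEffects(g, c(5, 25), scenario = "2:0", seed = 2)
#' y <- simulateTrait(g, cfg, seed = 3)
#' @export
simulateTrait <- function(G, config, seed = NULL) {
  stopifnot(methods::is(config, "CausalConfig"))
  methods::validObject(config)
  Xall <- if (methods::is(G, "GenotypePanel")) dosages(G) else as.matrix(G)
  stopifnot(all(config@causalIdx <= ncol(Xall)))
  .setSeed(seed)
  X <- Xall[, config@causalIdx, drop = FALSE]
  y <- as.vector(X %*% (config@sign * config@beta)) + rnorm(nrow(X))
  attr(y, "seed") <- seed
  y
}
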