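#' Accessors for GenotypePanel and result classes
#'
#' `dosages()` returns the n x m samples-by-variants dosage matrix (the
#' regression orientation); `mafs()`, `variantPositions()` and
#' `variantIds()` return per-variant metadata; `nSamples()` and
#' `nVariants()` the panel dimensions. `peaks()` returns the peak table of a
#' [StepwisePeaks-class] object and `stopReason()` its termination reason.
#'
#' @param x a [GenotypePanel-class] or [StepwisePeaks-class] object.
#' @return See details above; metadata vectors are named by variant id.
#' @examples
#' g <- GenotypePanel(matrix(c(0, 1, 2, 0, 0, 1), nrow = 3))
#' dosages(g)
#' nVariants(g)
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @rdname panel-accessors
#' @export
setGeneric("mafs", function(x) standardGeneric("mafs"))

#' @rdname panel-accessors
#' @export
setGeneric("variantPositions", function(x) standardGeneric("variantPositions"))

#' @rdname panel-accessors
#' @export
setGeneric("variantIds", function(x) standardGeneric("variantIds"))

#' @rdname panel-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname panel-accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @rdname panel-accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname panel-accessors
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' @rdname panel-accessors
#' @export
setMethod("dosages", "GenotypePanel", function(x)
  t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname panel-accessors
#' @export
setMethod("mafs", "GenotypePanel", function(x)
  setNames(SummarizedExperiment::rowData(x)$maf, rownames(x)))

#' @rdname panel-accessors
#' @export
setMethod("variantPositions", "GenotypePanel", function(x)
  setNames(SummarizedExperiment::rowData(x)$position, rownames(x)))

#' @rdname panel-accessors
#' @export
setMethod("variantIds", "GenotypePanel", function(x) rownames(x))

#' @rdname panel-accessors
#' @export
setMethod("nSamples", "GenotypePanel", function(x) ncol(x))

#' @rdname panel-accessors
#' @export
setMethod("nVariants", "GenotypePanel", function(x) nrow(x))

#' @rdname panel-accessors
#' @export
setMethod("peaks", "StepwisePeaks", function(x) x@peaks)

#' @rdname panel-accessors
#' @export
setMethod("stopReason", "StepwisePeaks", function(x) x@stopReason)
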