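#' @rdname PseudoBulkDataset-class
#' @param x object
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname PseudoBulkDataset-class
#' @export
setGeneric("simProvenance", function(x) standardGeneric("simProvenance"))

#' @rdname FractionMatrix-class
#' @param x object
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname FractionMatrix-class
#' @export
setGeneric("sumConstrained", function(x) standardGeneric("sumConstrained"))

#' @rdname FractionMatrix-class
#' @export
setGeneric("solverInfo", function(x) standardGeneric("solverInfo"))

#' @rdname SignatureMatrix-class
#' @param x object
#' @export
setGeneric("signatureValues", function(x) standardGeneric("signatureValues"))

#' @rdname SignatureMatrix-class
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname SignatureMatrix-class
#' @export
setGeneric("signatureTypes", function(x) standardGeneric("signatureTypes"))

#' @rdname SignatureMatrix-class
#' @export
setGeneric("buildMeta", function(x) standardGeneric("buildMeta"))

#' @rdname SingleCellReference-class
#' @param x object
#' @param level annotation resolution: `"fine"`, `"normal"` or `"coarse"`.
#' @export
setGeneric("cellTypeLabels",
           function(x, level = "fine") standardGeneric("cellTypeLabels"))

#' @rdname SingleCellReference-class
#' @export
setGeneric("typeProportions",
           function(x, level = "fine") standardGeneric("typeProportions"))

#' @rdname SingleCellReference-class
#' @param from,to hierarchy levels to map between (fine -> coarser).
#' @export
setGeneric("hierarchyMap",
           function(x, from = "fine", to = "coarse")
             standardGeneric("hierarchyMap"))

#' @rdname SingleCellReference-class
#' @export
setGeneric("markerGenes", function(x) standardGeneric("markerGenes"))

#' @rdname ScalingFactors-class
#' @param x object
#' @export
setGeneric("factorValues", function(x) standardGeneric("factorValues"))
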