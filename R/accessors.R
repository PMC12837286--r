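#' @rdname PseudoBulkDataset-class
#' @export
setMethod("groundTruth", "PseudoBulkDataset", function(x) {
  S4Vectors::metadata(x)$ground_truth
})

#' @rdname PseudoBulkDataset-class
#' @export
setMethod("simProvenance", "PseudoBulkDataset", function(x) {
  S4Vectors::metadata(x)$provenance
})

#' @rdname FractionMatrix-class
#' @export
setMethod("fractions", "FractionMatrix", function(x) x@values)

#' @rdname FractionMatrix-class
#' @export
setMethod("sumConstrained", "FractionMatrix", function(x) x@sumConstrained)

#' @rdname FractionMatrix-class
#' @export
setMethod("solverInfo", "FractionMatrix", function(x) x@solverInfo)

#' @rdname SignatureMatrix-class
#' @export
setMethod("signatureValues", "SignatureMatrix", function(x) x@values)

#' @rdname SignatureMatrix-class
#' @export
setMethod("signatureGenes", "SignatureMatrix", function(x) rownames(x@values))

#' @rdname SignatureMatrix-class
#' @export
setMethod("signatureTypes", "SignatureMatrix", function(x) colnames(x@values))

#' @rdname SignatureMatrix-class
#' @export
setMethod("buildMeta", "SignatureMatrix", function(x) x@buildMeta)

#' @rdname SingleCellReference-class
#' @export
setMethod("cellTypeLabels", "SingleCellReference", function(x, level = "fine") {
  level <- match.arg(level, c("fine", "normal", "coarse"))
  as.character(SummarizedExperiment::colData(x)[[level]])
})

#' @rdname SingleCellReference-class
#' @export
setMethod("typeProportions", "SingleCellReference", function(x, level = "fine") {
  lab <- cellTypeLabels(x, level)
  tab <- table(lab)
  p <- as.numeric(tab) / length(lab)
  names(p) <- names(tab)
  p[order(names(p))]
})

#' @rdname SingleCellReference-class
#' @export
setMethod("hierarchyMap", "SingleCellReference",
          function(x, from = "fine", to = "coarse") {
  from <- match.arg(from, c("fine", "normal", "coarse"))
  to <- match.arg(to, c("fine", "normal", "coarse"))
  lo <- cellTypeLabels(x, from)
  hi <- cellTypeLabels(x, to)
  tab <- unique(data.frame(lo = lo, hi = hi, stringsAsFactors = FALSE))
  if (anyDuplicated(tab$lo)) {
    stop(sprintf("label(s) at level '%s' map to multiple '%s' labels", from, to),
         call. = FALSE)
  }
  stats::setNames(tab$hi, tab$lo)
})

#' @rdname SingleCellReference-class
#' @export
setMethod("markerGenes", "SingleCellReference", function(x) {
  mk <- S4Vectors::metadata(x)$markers
  if (is.null(mk)) list() else mk
})

#' @rdname ScalingFactors-class
#' @export
setMethod("factorValues", "ScalingFactors", function(x) x@values)

setMethod("show", "SingleCellReference", function(object) {
  cat(sprintf("SingleCellReference: %d genes x %d cells\n",
              nrow(object), ncol(object)))
  for (lv in c("coarse", "normal", "fine")) {
    cat(sprintf("  %s types: %d\n", lv,
                length(unique(cellTypeLabels(object, lv)))))
  }
  cat(sprintf("  donors: %d\n",
              length(unique(SummarizedExperiment::colData(object)$donor_id))))
  invisible(object)
})

setMethod("show", "SignatureMatrix", function(object) {
  cat(sprintf("SignatureMatrix: %d genes x %d cell types\n",
              nrow(object@values), ncol(object@values)))
  cat("  types:", paste(colnames(object@values), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "FractionMatrix", function(object) {
  cat(sprintf("FractionMatrix: %d samples x %d cell types (%s)\n",
              nrow(object@values), ncol(object@values),
              if (object@sumConstrained) "sum-to-one" else "unconstrained"))
  invisible(object)
})

setMethod("show", "EvaluationReport", function(object) {
  g <- if (object@globalUndefined) "undefined" else
    sprintf("%.4f", object@globalPearson)
  cat(sprintf("EvaluationReport: %d samples, %d cell types\n",
              object@nSamples, object@nTypes))
  cat(sprintf("  global Pearson r: %s\n", g))
  cat(sprintf("  mean per-sample RMSE: %.4f\n", mean(object@perSampleRMSE)))
  invisible(object)
})

setMethod("show", "SpilloverReport", function(object) {
  cat(sprintf("SpilloverReport: %d pure cell types\n",
              nrow(object@spillMatrix)))
  cat(sprintf("  total spillover: %.2f%%\n", object@totalSpilloverPct))
  invisible(object)
})

setMethod("show", "ScalingFactors", function(object) {
  cat(sprintf("ScalingFactors (mode '%s'): %d cells, range [%.3f, %.3f]\n",
              object@mode, length(object@values),
              min(object@values), max(object@values)))
  invisible(object)
})
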