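#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

#' Annotated single-cell reference
#'
#' A [SingleCellExperiment::SingleCellExperiment] carrying a gene-by-cell
#' count matrix plus the per-cell metadata required by the benchmarking
#' workflow: a three-level cell-type label hierarchy (`fine`, `normal`,
#' `coarse`), a donor label and a mitochondrial-fraction QC metric.
#'
#' The label hierarchy is encoded as three `colData` columns rather than a
#' tree object; validity requires every fine label to map to exactly one
#' normal and one coarse label.
#'
#' @slot .Data see [SingleCellExperiment::SingleCellExperiment]
#' @export
setClass("SingleCellReference", contains = "SingleCellExperiment")

.validSingleCellReference <- function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  needed <- c("fine", "normal", "coarse", "donor_id", "mito_fraction")
  missing <- setdiff(needed, colnames(cd))
  if (length(missing)) {
    return(sprintf("missing colData column(s): %s",
                   paste(missing, collapse = ", ")))
  }
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'counts' is required")
  }
  mf <- cd$mito_fraction
  if (any(is.na(mf)) || any(mf < 0) || any(mf > 1)) {
    msg <- c(msg, "mito_fraction must lie in [0, 1]")
  }
  if (any(is.na(cd$fine)) || any(cd$fine == "")) {
    msg <- c(msg, "every cell must carry a fine label")
  }
  # hierarchy totality: each fine label maps to exactly one normal/coarse
  for (lv in c("normal", "coarse")) {
    tab <- unique(data.frame(fine = as.character(cd$fine),
                             up = as.character(cd[[lv]])))
    dup <- unique(tab$fine[duplicated(tab$fine)])
    if (length(dup)) {
      msg <- c(msg, sprintf(
        "fine label(s) mapped to multiple %s labels: %s",
        lv, paste(dup, collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("SingleCellReference", .validSingleCellReference)

#' Construct a SingleCellReference
#'
#' @param counts gene-by-cell non-negative count matrix (coerced to sparse).
#' @param annotations data.frame with one row per cell and columns
#'   `cell_id`, `fine`, `normal`, `coarse`, `donor_id`, `mito_fraction`.
#' @param markers optional named list (cell type -> character vector of
#'   marker gene ids) recorded in `metadata()$markers`.
#' @return a [SingleCellReference-class] object.
#' @export
SingleCellReference <- function(counts, annotations, markers = list()) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (ncol(counts) != nrow(annotations)) {
    stop(sprintf("counts has %d cells but annotations has %d rows",
                 ncol(counts), nrow(annotations)), call. = FALSE)
  }
  if (!is.null(annotations$cell_id)) {
    colnames(counts) <- as.character(annotations$cell_id)
  }
  cd <- S4Vectors::DataFrame(
    fine = as.character(annotations$fine),
    normal = as.character(annotations$normal),
    coarse = as.character(annotations$coarse),
    donor_id = as.character(annotations$donor_id),
    mito_fraction = as.numeric(annotations$mito_fraction),
    row.names = colnames(counts))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  obj <- methods::new("SingleCellReference", sce)
  S4Vectors::metadata(obj)$markers <- markers
  methods::validObject(obj)
  obj
}

#' Simulated pseudo-bulk dataset
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a gene-by-sample
#' `counts` assay, a ground-truth fraction table (samples x cell types,
#' cell-count fractions) in `metadata()$ground_truth`, and the simulation
#' provenance (scenario, seeds, bias mode) in `metadata()$provenance`.
#'
#' @export
setClass("PseudoBulkDataset", contains = "SummarizedExperiment")

.validPseudoBulkDataset <- function(object) {
  gt <- S4Vectors::metadata(object)$ground_truth
  if (is.null(gt)) return("metadata()$ground_truth is required")
  if (nrow(gt) != ncol(object)) {
    return(sprintf("ground truth has %d rows but dataset has %d samples",
                   nrow(gt), ncol(object)))
  }
  rs <- rowSums(gt)
  if (any(abs(rs - 1) > 1e-9)) {
    return("ground-truth rows must sum to 1 within 1e-9")
  }
  TRUE
}
setValidity("PseudoBulkDataset", .validPseudoBulkDataset)

#' Signature matrix
#'
#' Gene-by-cell-type reference expression profile (mean CPM per type over a
#' selected marker gene set) used by the reference solvers, together with
#' build metadata (p-value cutoff, test, gene cap, source reference id).
#'
#' @slot values non-negative gene x cell-type matrix with dimnames.
#' @slot buildMeta list of build parameters.
#' @export
setClass("SignatureMatrix",
         representation(values = "matrix", buildMeta = "list"))

.validSignatureMatrix <- function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v))) {
    return("values must carry gene rownames and cell-type colnames")
  }
  if (ncol(v) < 2) return("a signature needs at least 2 cell types")
  if (nrow(v) < 1) return("a signature needs at least 1 gene")
  if (any(v < 0)) return("signature values must be non-negative")
  if (any(rowSums(v) == 0)) return("all-zero gene rows are not allowed")
  TRUE
}
setValidity("SignatureMatrix", .validSignatureMatrix)

#' Estimated (or true) cell-type fraction matrix
#'
#' Sample-by-cell-type non-negative matrix. When `sumConstrained` is `TRUE`
#' every row sums to 1 (within 1e-9), the convention of sum-to-one
#' deconvolution output. Solver provenance (gene overlap, iterations,
#' convergence flags) is kept in `solverInfo`.
#'
#' @slot values sample x cell-type matrix.
#' @slot sumConstrained logical flag.
#' @slot solverInfo list.
#' @export
setClass("FractionMatrix",
         representation(values = "matrix", sumConstrained = "logical",
                        solverInfo = "list"),
         prototype(sumConstrained = FALSE, solverInfo = list()))

.validFractionMatrix <- function(object) {
  v <- object@values
  if (any(v < -1e-12)) return("fractions must be non-negative")
  if (is.null(colnames(v))) return("cell-type column names are required")
  if (isTRUE(object@sumConstrained)) {
    rs <- rowSums(v)
    if (any(abs(rs - 1) > 1e-9)) {
      return("sum_constrained rows must sum to 1 within 1e-9")
    }
  }
  TRUE
}
setValidity("FractionMatrix", .validFractionMatrix)

#' Construct a FractionMatrix
#' @param values sample x cell-type non-negative matrix.
#' @param sumConstrained logical; assert rows sum to one.
#' @param solverInfo provenance list.
#' @return a [FractionMatrix-class].
#' @export
FractionMatrix <- function(values, sumConstrained = FALSE,
                           solverInfo = list()) {
  values <- as.matrix(values)
  values[values < 0 & values > -1e-12] <- 0
  methods::new("FractionMatrix", values = values,
               sumConstrained = sumConstrained, solverInfo = solverInfo)
}

#' Evaluation report
#'
#' Global and per-cell-type agreement between true and estimated fractions:
#' pooled (global) Pearson correlation, per-type Pearson/RMSE/MAE/MAPE, and
#' per-sample RMSE. Undefined correlations (constant vectors, e.g. a type
#' estimated as all zeros) carry an explicit flag instead of silently
#' propagating NaN.
#'
#' @slot globalPearson numeric (NA when undefined).
#' @slot globalUndefined logical.
#' @slot perType data.frame with one row per cell type.
#' @slot perSampleRMSE named numeric.
#' @slot nSamples,nTypes integer.
#' @slot meta list (e.g. provenance for pairing checks).
#' @export
setClass("EvaluationReport",
         representation(globalPearson = "numeric", globalUndefined = "logical",
                        perType = "data.frame", perSampleRMSE = "numeric",
                        nSamples = "integer", nTypes = "integer",
                        meta = "list"),
         prototype(meta = list()))

#' Spillover report
#'
#' For every pure simulated cell type, the mean estimated percentage mass on
#' each target type. The diagonal is the correctly assigned percentage; rows
#' are compositional (sum to 100).
#'
#' @slot spillMatrix true-type x estimated-type matrix of mean percentages.
#' @slot correctPct named numeric, the diagonal.
#' @slot totalSpilloverPct mean over types of (100 - correct).
#' @export
setClass("SpilloverReport",
         representation(spillMatrix = "matrix", correctPct = "numeric",
                        totalSpilloverPct = "numeric"))

.validSpilloverReport <- function(object) {
  rs <- rowSums(object@spillMatrix)
  if (any(abs(rs - 100) > 1e-6)) {
    return("spillover rows must sum to 100% within 1e-6")
  }
  TRUE
}
setValidity("SpilloverReport", .validSpilloverReport)

#' Per-cell mRNA-content scaling factors
#'
#' In mode `expressed_genes` the factor of cell c is its number of expressed
#' (nonzero) genes divided by the mean over all cells, the proxy used to
#' model cell-type mRNA-content bias; factors therefore have mean 1 so the
#' bias changes relative, not absolute, contributions. In mode `none` all
#' factors are 1.
#'
#' @slot values named numeric, one per cell.
#' @slot mode `"expressed_genes"` or `"none"`.
#' @export
setClass("ScalingFactors",
         representation(values = "numeric", mode = "character"))

.validScalingFactors <- function(object) {
  if (!object@mode %in% c("expressed_genes", "none")) {
    return("mode must be 'expressed_genes' or 'none'")
  }
  if (any(object@values <= 0)) return("scaling factors must be positive")
  if (object@mode == "none" && any(object@values != 1)) {
    return("mode 'none' requires all factors equal to 1")
  }
  TRUE
}
setValidity("ScalingFactors", .validScalingFactors)
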