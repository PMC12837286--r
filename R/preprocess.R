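#' Median absolute deviation without consistency rescaling
#'
#' `median(|x_i - median(x)|)`, the raw MAD used for cell quality control;
#' unlike [stats::mad()] no normal-consistency constant is applied.
#'
#' @param values non-empty numeric vector.
#' @return non-negative number.
#' @examples
#' madStat(c(1, 2, 3))  # 1
#' @export
madStat <- function(values) {
  if (length(values) == 0) stop("empty vector", call. = FALSE)
  stats::median(abs(values - stats::median(values)))
}

#' QC thresholds for MAD-based outlier filtering
#'
#' Defaults follow common practice for droplet scRNA-seq: 5 MADs for total
#' counts and expressed-gene counts (two-sided), 3 MADs for the
#' mitochondrial fraction (upper-sided only, since low mito content is not
#' a quality problem).
#'
#' @param nCountsMads,nGenesMads,mitoMads positive multipliers.
#' @return a named list.
#' @export
qcThresholds <- function(nCountsMads = 5, nGenesMads = 5, mitoMads = 3) {
  stopifnot(nCountsMads > 0, nGenesMads > 0, mitoMads > 0)
  list(n_counts_mads = nCountsMads, n_genes_mads = nGenesMads,
       mito_mads = mitoMads)
}

#' Remove outlier cells by MAD deviation
#'
#' A cell is an outlier when its total counts or expressed-gene count
#' deviates from the metric's median by more than k·MAD (two-sided), or its
#' mitochondrial fraction exceeds the median by more than k·MAD
#' (upper-sided). Retained cells keep their original order; removed cell
#' ids are recorded in `metadata()$qc$removed_cells`.
#'
#' @param reference a [SingleCellReference-class].
#' @param thresholds list from [qcThresholds()].
#' @return the filtered reference.
#' @export
madOutlierFilter <- function(reference, thresholds = qcThresholds()) {
  cnt <- SummarizedExperiment::assay(reference, "counts")
  totals <- Matrix::colSums(cnt)
  ngene <- .colNonzero(cnt)
  mito <- SummarizedExperiment::colData(reference)$mito_fraction

  twoSided <- function(x, k) abs(x - stats::median(x)) > k * madStat(x)
  upper <- function(x, k) (x - stats::median(x)) > k * madStat(x)

  out <- twoSided(totals, thresholds$n_counts_mads) |
    twoSided(ngene, thresholds$n_genes_mads) |
    upper(mito, thresholds$mito_mads)
  if (all(out)) stop("empty reference: all cells flagged as outliers",
                     call. = FALSE)
  res <- reference[, !out]
  qc <- S4Vectors::metadata(res)$qc
  qc$removed_cells <- colnames(reference)[out]
  qc$thresholds <- thresholds
  S4Vectors::metadata(res)$qc <- qc
  res
}

#' Counts-per-million normalization
#'
#' Scales every column (cell or sample) to sum to one million, preserving
#' within-column expression ratios. Idempotent.
#'
#' @param counts gene x cell (or gene x sample) matrix, sparse or dense.
#' @return matrix of the same shape and class family.
#' @examples
#' cpmNormalize(matrix(c(1, 1, 2), ncol = 1))
#' @export
cpmNormalize <- function(counts) {
  cs <- if (methods::is(counts, "Matrix")) Matrix::colSums(counts) else
    colSums(counts)
  zero <- which(cs == 0)
  if (length(zero)) {
    nm <- if (!is.null(colnames(counts))) colnames(counts)[zero[1]] else
      as.character(zero[1])
    stop(sprintf("zero-sum column: %s", nm), call. = FALSE)
  }
  if (methods::is(counts, "Matrix")) {
    out <- counts %*% Matrix::Diagonal(x = 1e6 / cs)
    dimnames(out) <- dimnames(counts)
    methods::as(out, "CsparseMatrix")
  } else {
    sweep(counts, 2, cs / 1e6, "/")
  }
}

#' Subsample a reference by cell type
#'
#' Three rules used when preparing training references:
#' \describe{
#'   \item{`fraction_per_type`}{keep `ceiling(param * n_t)` cells of every
#'     type t, except types with fewer than `minGuard` cells, which are
#'     kept whole (the 10\%-per-type rule).}
#'   \item{`total_proportional`}{target `param` cells in total with
#'     per-type counts assigned by largest-remainder apportionment so
#'     proportions match the full reference; types below `minGuard` are
#'     kept whole (the fixed-total rule, e.g. 15,000 cells).}
#'   \item{`cap_per_type`}{keep at most `param` cells per type (e.g. the
#'     500-cells-per-type training rule).}
#' }
#' Sampling is without replacement, seed-deterministic, and preserves cell
#' order and all labels.
#'
#' @param reference a [SingleCellReference-class].
#' @param mode one of `"fraction_per_type"`, `"total_proportional"`,
#'   `"cap_per_type"`.
#' @param param fraction in (0,1], total cell count, or per-type cap.
#' @param minGuard types smaller than this are never subsampled (ignored by
#'   `cap_per_type`).
#' @param seed integer seed.
#' @param level annotation level defining "type".
#' @return the subsampled reference.
#' @export
subsampleReference <- function(reference, mode, param, minGuard = 20, seed,
                               level = "fine") {
  mode <- match.arg(mode,
                    c("fraction_per_type", "total_proportional", "cap_per_type"))
  lab <- cellTypeLabels(reference, level)
  types <- sort(unique(lab))
  n <- stats::setNames(as.integer(table(lab)[types]), types)

  keepCount <- switch(mode,
    fraction_per_type = {
      if (param <= 0 || param > 1) {
        stop("fraction_per_type needs param in (0, 1]", call. = FALSE)
      }
      ifelse(n < minGuard, n, ceiling(param * n))
    },
    total_proportional = {
      if (param < length(types)) {
        stop("total_proportional needs param >= number of types",
             call. = FALSE)
      }
      kc <- n
      protected <- n < minGuard
      remaining <- max(0L, as.integer(param) - sum(n[protected]))
      open <- !protected
      # apportion, clamping at type sizes and redistributing the excess
      repeat {
        if (!any(open) || remaining <= 0) { kc[open] <- 0L; break }
        alloc <- .largestRemainder(n[open], min(remaining, sum(n[open])))
        names(alloc) <- names(n)[open]
        over <- alloc > n[open]
        if (!any(over)) { kc[open] <- alloc; break }
        full <- names(n)[open][over]
        kc[full] <- n[full]
        remaining <- remaining - sum(n[full])
        open[match(full, names(n))] <- FALSE
      }
      kc
    },
    cap_per_type = {
      if (param < 1) stop("cap_per_type needs param >= 1", call. = FALSE)
      pmin(n, as.integer(param))
    })

  withr::with_seed(seed, {
    sel <- unlist(lapply(types, function(t) {
      idx <- which(lab == t)
      k <- keepCount[[t]]
      if (k >= length(idx)) idx else sort(sample(idx, k))
    }))
  })
  reference[, sort(sel)]
}
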