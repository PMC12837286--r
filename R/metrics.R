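## performance metrics: Pearson (global / per type), RMSE (per sample /
## per type), MAE, MAPE, and the paired-bias delta-RMSE

.asFractionValues <- function(x) {
  if (methods::is(x, "FractionMatrix")) fractions(x) else as.matrix(x)
}

.bothVectors <- function(a, b) {
  is.null(dim(a)) && is.null(dim(b)) &&
    !methods::is(a, "FractionMatrix") && !methods::is(b, "FractionMatrix")
}

#' Pearson correlation between true and estimated fractions
#'
#' `scope = "global"` pools all (sample, type) pairs into one correlation;
#' `scope = "per_type"` correlates over samples within each type column.
#' Constant vectors (e.g. a cell type estimated as all zeros) yield `NA`
#' with an `undefined` flag instead of a propagated NaN.
#'
#' @param truth,est sample x type matrices or [FractionMatrix-class]
#'   objects; aligned by sample and type labels (mismatch is an error
#'   listing the symmetric difference).
#' @param scope `"global"` or `"per_type"`.
#' @return for `"global"` a single numeric with attribute `undefined`;
#'   for `"per_type"` a named numeric with attribute `undefined` (logical
#'   per type).
#' @export
pearsonR <- function(truth, est, scope = c("global", "per_type")) {
  scope <- match.arg(scope)
  al <- .alignByLabel(.asFractionValues(truth), .asFractionValues(est))
  safeCor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      structure(NA_real_, undefined = TRUE)
    } else {
      structure(stats::cor(x, y), undefined = FALSE)
    }
  }
  if (scope == "global") {
    return(safeCor(as.numeric(al$truth), as.numeric(al$est)))
  }
  r <- numeric(ncol(al$truth)); und <- logical(ncol(al$truth))
  for (k in seq_len(ncol(al$truth))) {
    v <- safeCor(al$truth[, k], al$est[, k])
    r[k] <- as.numeric(v); und[k] <- attr(v, "undefined")
  }
  names(r) <- colnames(al$truth)
  attr(r, "undefined") <- stats::setNames(und, colnames(al$truth))
  r
}

.rmse <- function(a, b) sqrt(mean((a - b)^2))

#' Root-mean-square error per sample
#'
#' `sqrt(mean((x_c - y_c)^2))` over the cell types of each sample.
#'
#' @param truth,est numeric vectors (one sample) or sample x type matrices.
#' @return a number, or a named numeric per sample.
#' @export
rmsePerSample <- function(truth, est) {
  if (.bothVectors(truth, est)) {
    if (length(truth) != length(est)) stop("length mismatch", call. = FALSE)
    return(.rmse(truth, est))
  }
  al <- .alignByLabel(.asFractionValues(truth), .asFractionValues(est))
  stats::setNames(
    sapply(seq_len(nrow(al$truth)),
           function(i) .rmse(al$truth[i, ], al$est[i, ])),
    rownames(al$truth))
}

#' Root-mean-square error per cell type
#'
#' `sqrt(mean((x_s - y_s)^2))` over the samples of each type.
#'
#' @param truth,est numeric vectors (one type) or sample x type matrices.
#' @return a number, or a named numeric per type.
#' @export
rmsePerType <- function(truth, est) {
  if (.bothVectors(truth, est)) {
    if (length(truth) != length(est)) stop("length mismatch", call. = FALSE)
    return(.rmse(truth, est))
  }
  al <- .alignByLabel(.asFractionValues(truth), .asFractionValues(est))
  stats::setNames(
    sapply(seq_len(ncol(al$truth)),
           function(k) .rmse(al$truth[, k], al$est[, k])),
    colnames(al$truth))
}

#' Mean absolute error per cell type
#' @param truth,est vectors or sample x type matrices.
#' @return number or named numeric per type.
#' @export
maePerType <- function(truth, est) {
  if (.bothVectors(truth, est)) {
    if (length(truth) != length(est)) stop("length mismatch", call. = FALSE)
    return(mean(abs(truth - est)))
  }
  al <- .alignByLabel(.asFractionValues(truth), .asFractionValues(est))
  stats::setNames(colMeans(abs(al$truth - al$est)), colnames(al$truth))
}

#' Mean absolute percentage error per cell type
#'
#' `mean(|(x - y) / x|)` over entries with truth x > 0; zero-truth entries
#' are excluded and their count reported via the `n_excluded` attribute.
#' All-zero truth yields `NA` with `undefined = TRUE`.
#'
#' @param truth,est vectors or sample x type matrices.
#' @return number(s) with attributes `n_excluded` and `undefined`.
#' @export
mapePerType <- function(truth, est) {
  mape1 <- function(x, y) {
    pos <- x > 0
    if (!any(pos)) {
      return(structure(NA_real_, n_excluded = sum(!pos), undefined = TRUE))
    }
    structure(mean(abs((x[pos] - y[pos]) / x[pos])),
              n_excluded = sum(!pos), undefined = FALSE)
  }
  if (.bothVectors(truth, est)) {
    if (length(truth) != length(est)) stop("length mismatch", call. = FALSE)
    return(mape1(truth, est))
  }
  al <- .alignByLabel(.asFractionValues(truth), .asFractionValues(est))
  vals <- numeric(ncol(al$truth)); nex <- integer(ncol(al$truth))
  und <- logical(ncol(al$truth))
  for (k in seq_len(ncol(al$truth))) {
    v <- mape1(al$truth[, k], al$est[, k])
    vals[k] <- as.numeric(v)
    nex[k] <- attr(v, "n_excluded"); und[k] <- attr(v, "undefined")
  }
  names(vals) <- colnames(al$truth)
  attr(vals, "n_excluded") <- stats::setNames(nex, names(vals))
  attr(vals, "undefined") <- stats::setNames(und, names(vals))
  vals
}

#' Full evaluation of estimated against true fractions
#'
#' @param truth,est sample x type matrices or [FractionMatrix-class]
#'   objects, aligned by label.
#' @param meta optional provenance list (e.g. the simulation provenance of
#'   the dataset the estimates were computed on), used by
#'   [deltaRmseBias()] to verify pairing.
#' @return an [EvaluationReport-class].
#' @export
evaluateFractions <- function(truth, est, meta = list()) {
  al <- .alignByLabel(.asFractionValues(truth), .asFractionValues(est))
  g <- pearsonR(al$truth, al$est, "global")
  pt <- pearsonR(al$truth, al$est, "per_type")
  rc <- rmsePerType(al$truth, al$est)
  mae <- maePerType(al$truth, al$est)
  mape <- mapePerType(al$truth, al$est)
  perType <- data.frame(
    cell_type = colnames(al$truth),
    pearson = as.numeric(pt),
    pearson_undefined = unname(attr(pt, "undefined")),
    rmse = as.numeric(rc),
    mae = as.numeric(mae),
    mape = as.numeric(mape),
    mape_undefined = unname(attr(mape, "undefined")),
    mape_n_excluded = unname(attr(mape, "n_excluded")),
    row.names = NULL)
  methods::new("EvaluationReport",
               globalPearson = as.numeric(g),
               globalUndefined = isTRUE(attr(g, "undefined")),
               perType = perType,
               perSampleRMSE = rmsePerSample(al$truth, al$est),
               nSamples = nrow(al$truth), nTypes = ncol(al$truth),
               meta = meta)
}

#' @rdname EvaluationReport-class
#' @param x an EvaluationReport
#' @export
perTypeMetrics <- function(x) {
  stopifnot(methods::is(x, "EvaluationReport"))
  x@perType
}

#' @rdname EvaluationReport-class
#' @export
sampleRMSE <- function(x) {
  stopifnot(methods::is(x, "EvaluationReport"))
  x@perSampleRMSE
}

#' @rdname EvaluationReport-class
#' @export
globalPearson <- function(x) {
  stopifnot(methods::is(x, "EvaluationReport"))
  structure(x@globalPearson, undefined = x@globalUndefined)
}

#' Per-type RMSE difference between paired bias and no-bias runs
#'
#' `delta_t = RMSE_t(with bias) - RMSE_t(without bias)` on evaluation
#' reports built from paired-seed datasets. A positive value means the
#' pipeline does not correct the mRNA-content bias for that type. When
#' both reports carry simulation provenance, pairing (identical sample
#' seeds) is verified and a mismatch is an error.
#'
#' @param reportWithBias,reportWithout [EvaluationReport-class] objects
#'   over the same cell-type set.
#' @return named numeric of signed per-type differences.
#' @export
deltaRmseBias <- function(reportWithBias, reportWithout) {
  a <- perTypeMetrics(reportWithBias); b <- perTypeMetrics(reportWithout)
  if (!setequal(a$cell_type, b$cell_type)) {
    stop("reports cover different cell-type sets", call. = FALSE)
  }
  sa <- reportWithBias@meta$sample_seeds
  sb <- reportWithout@meta$sample_seeds
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    stop("unpaired reports: the two arms used different sample seeds",
         call. = FALSE)
  }
  b <- b[match(a$cell_type, b$cell_type), ]
  stats::setNames(a$rmse - b$rmse, a$cell_type)
}
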