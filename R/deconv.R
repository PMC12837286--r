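## reference solvers: constrained NNLS baseline and a dampened weighted
## least-squares solver, plus fraction normalization and aggregation

#' @importFrom pracma lsqnonneg
NULL

# intersect signature and bulk gene sets (exact, case-sensitive ids) and
# CPM-normalize the bulk columns; errors below the overlap threshold
.prepareSolve <- function(signature, bulk) {
  S <- signatureValues(signature)
  if (methods::is(bulk, "PseudoBulkDataset")) {
    bulk <- SummarizedExperiment::assay(bulk, "counts")
  }
  bulk <- as.matrix(bulk)
  if (is.null(colnames(bulk))) {
    colnames(bulk) <- sprintf("sample%03d", seq_len(ncol(bulk)))
  }
  common <- intersect(rownames(S), rownames(bulk))
  need <- 2 * ncol(S)
  if (length(common) < need) {
    stop(sprintf(
      "gene overlap too small: %d shared genes, need >= %d (2 x %d types)",
      length(common), need, ncol(S)), call. = FALSE)
  }
  zero <- colSums(bulk) == 0
  if (any(zero)) {
    stop(sprintf("all-zero bulk column(s): %s",
                 paste(colnames(bulk)[zero], collapse = ", ")), call. = FALSE)
  }
  bulk <- cpmNormalize(bulk)
  list(S = S[common, , drop = FALSE], B = bulk[common, , drop = FALSE],
       overlap = length(common))
}

#' Non-negative least squares deconvolution
#'
#' For each bulk sample solves `min || S f - b ||_2` subject to `f >= 0`
#' (Lawson-Hanson active set via [pracma::lsqnonneg()]) on the intersected
#' gene set, with the bulk column CPM-normalized first, then rescales the
#' estimate to sum to 1. The baseline least-squares core shared by
#' signature-based deconvolution methods.
#'
#' @param signature a [SignatureMatrix-class].
#' @param bulk gene x sample matrix or [PseudoBulkDataset-class].
#' @return a sum-constrained [FractionMatrix-class]; `solverInfo()` records
#'   the gene overlap used.
#' @export
nnlsDeconvolve <- function(signature, bulk) {
  prep <- .prepareSolve(signature, bulk)
  S <- prep$S; B <- prep$B
  est <- matrix(0, ncol(B), ncol(S),
                dimnames = list(colnames(B), colnames(S)))
  for (j in seq_len(ncol(B))) {
    f <- pracma::lsqnonneg(S, B[, j])$x
    if (sum(f) == 0) {
      stop(sprintf("solver returned all-zero fractions for sample %s",
                   colnames(B)[j]), call. = FALSE)
    }
    est[j, ] <- f / sum(f)
  }
  FractionMatrix(est, sumConstrained = TRUE,
                 solverInfo = list(solver = "nnls", gene_overlap = prep$overlap))
}

# weighted NNLS: scale rows by sqrt(w)
.wnnls <- function(S, b, w) {
  sw <- sqrt(w)
  pracma::lsqnonneg(S * sw, b * sw)$x
}

# pick the dampening exponent j (weights capped at 2^j) by deterministic
# k-fold cross-validation over genes, minimizing the held-out weighted
# residual
.pickDampening <- function(S, b, ws, grid, folds) {
  n <- nrow(S)
  fold <- (seq_len(n) - 1L) %% folds
  best <- grid[1]; bestScore <- Inf
  maxRatio <- max(ws)
  for (j in grid) {
    wc <- pmin(ws, 2^j)
    score <- 0
    for (k in seq_len(folds) - 1L) {
      tr <- fold != k
      f <- .wnnls(S[tr, , drop = FALSE], b[tr], wc[tr])
      resid <- as.numeric(S[!tr, , drop = FALSE] %*% f) - b[!tr]
      score <- score + sum(wc[!tr] * resid^2)
    }
    if (is.finite(score) && score < bestScore) {
      bestScore <- score; best <- j
    }
    if (2^j >= maxRatio) break  # larger caps change nothing
  }
  best
}

#' Dampened weighted least squares deconvolution
#'
#' Iteratively re-weighted constrained least squares: starting from the
#' NNLS solution, per-gene weights `w_g = 1 / max((S f)_g, eps)^2` are
#' capped at `2^j` (after scaling so the smallest weight is 1), where the
#' dampening exponent j is chosen once per sample by deterministic k-fold
#' cross-validation over genes, minimizing the held-out weighted residual
#' over the grid `j in 1..30`. Each iteration solves a weighted NNLS; the
#' loop stops when the infinity-norm change of the normalized fractions
#' falls below `tol` or after `maxIter` iterations. The dampening prevents
#' a handful of low-expression genes from dominating the fit while still
#' up-weighting the genes that carry the signal of rare cell types.
#'
#' @param signature a [SignatureMatrix-class].
#' @param bulk gene x sample matrix or [PseudoBulkDataset-class].
#' @param maxIter maximum iterations per sample.
#' @param tol convergence tolerance on the fraction change.
#' @param dampeningGrid candidate exponents for the weight cap.
#' @param cvFolds folds for the dampening cross-validation (genes are
#'   assigned round-robin, so the procedure is fully deterministic).
#' @param eps floor inside the weights, protecting undetected types.
#' @return a sum-constrained [FractionMatrix-class]; `solverInfo()` records
#'   iterations, chosen dampening exponents and per-sample convergence
#'   flags (non-convergence is flagged, never an error).
#' @export
dwlsDeconvolve <- function(signature, bulk, maxIter = 100, tol = 1e-6,
                           dampeningGrid = 1:30, cvFolds = 5, eps = 1e-8) {
  prep <- .prepareSolve(signature, bulk)
  S <- prep$S; B <- prep$B
  est <- matrix(0, ncol(B), ncol(S),
                dimnames = list(colnames(B), colnames(S)))
  iters <- integer(ncol(B)); conv <- logical(ncol(B)); damp <- integer(ncol(B))
  for (jcol in seq_len(ncol(B))) {
    b <- B[, jcol]
    f <- pracma::lsqnonneg(S, b)$x
    if (sum(f) == 0) {
      stop(sprintf("initial solve returned all-zero fractions for sample %s",
                   colnames(B)[jcol]), call. = FALSE)
    }
    w0 <- 1 / pmax(as.numeric(S %*% f), eps)^2
    ws0 <- w0 / min(w0)
    jdamp <- .pickDampening(S, b, ws0, dampeningGrid, cvFolds)
    fn <- f / sum(f)
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
      it <- it + 1L
      w <- 1 / pmax(as.numeric(S %*% f), eps)^2
      wc <- pmin(w / min(w), 2^jdamp)
      fNew <- .wnnls(S, b, wc)
      if (sum(fNew) == 0) break  # keep last iterate
      fnNew <- fNew / sum(fNew)
      delta <- max(abs(fnNew - fn))
      f <- fNew; fn <- fnNew
      if (delta < tol) { converged <- TRUE; break }
    }
    est[jcol, ] <- fn
    iters[jcol] <- it; conv[jcol] <- converged; damp[jcol] <- jdamp
  }
  FractionMatrix(est, sumConstrained = TRUE,
                 solverInfo = list(solver = "dwls", gene_overlap = prep$overlap,
                                   iterations = iters, dampening = damp,
                                   converged = conv,
                                   non_converged_samples =
                                     colnames(B)[!conv]))
}

#' Normalize fractions to sum to one per sample
#'
#' @param raw sample x type non-negative matrix or [FractionMatrix-class].
#' @return a sum-constrained [FractionMatrix-class].
#' @export
normalizeFractions <- function(raw) {
  info <- list()
  if (methods::is(raw, "FractionMatrix")) {
    info <- solverInfo(raw)
    raw <- fractions(raw)
  }
  raw <- as.matrix(raw)
  if (any(raw < 0)) stop("fractions must be non-negative", call. = FALSE)
  rs <- rowSums(raw)
  if (any(rs == 0)) {
    nm <- rownames(raw)[rs == 0]
    if (is.null(nm)) nm <- which(rs == 0)
    stop(sprintf("all-zero row(s): %s", paste(nm, collapse = ", ")),
         call. = FALSE)
  }
  FractionMatrix(raw / rs, sumConstrained = TRUE, solverInfo = info)
}

#' Aggregate fine-grained fractions to a coarser level
#'
#' Coarse entries are sums of the mapped fine entries; row sums are
#' preserved exactly, so aggregation commutes with normalization.
#'
#' @param fine a [FractionMatrix-class] (or sample x type matrix) at the
#'   finer resolution.
#' @param map named character: fine label -> coarse label, total on the
#'   fine type set.
#' @return a [FractionMatrix-class] at the coarse resolution.
#' @export
aggregateFractions <- function(fine, map) {
  constrained <- FALSE; info <- list()
  if (methods::is(fine, "FractionMatrix")) {
    constrained <- sumConstrained(fine)
    info <- solverInfo(fine)
    fine <- fractions(fine)
  }
  fine <- as.matrix(fine)
  unmapped <- setdiff(colnames(fine), names(map))
  if (length(unmapped)) {
    stop(sprintf("unmapped fine label(s): %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  coarse <- sort(unique(unname(map[colnames(fine)])))
  ind <- sapply(coarse, function(cc)
    as.numeric(map[colnames(fine)] == cc))
  out <- fine %*% ind
  colnames(out) <- coarse
  FractionMatrix(out, sumConstrained = constrained, solverInfo = info)
}
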