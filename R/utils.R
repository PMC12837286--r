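## internal helpers shared across modules

#' @importFrom Matrix colSums rowSums t readMM writeMM Diagonal sparseMatrix
NULL

# counts per column of nonzero entries; works for dgCMatrix and dense
.colNonzero <- function(m) {
  if (methods::is(m, "CsparseMatrix")) {
    nz <- diff(m@p)
    names(nz) <- colnames(m)
    nz
  } else {
    apply(m != 0, 2, sum)
  }
}

# largest-remainder apportionment of `total` units over non-negative quotas.
# Ties in the fractional part are broken by descending fractional part, then
# by position (label order).
.largestRemainder <- function(quotas, total) {
  stopifnot(all(quotas >= 0), total >= 0)
  if (sum(quotas) == 0) return(rep(0L, length(quotas)))
  q <- quotas / sum(quotas) * total
  base <- floor(q)
  rem <- q - base
  short <- as.integer(round(total - sum(base)))
  out <- as.integer(base)
  if (short > 0) {
    ord <- order(-rem, seq_along(rem))
    out[ord[seq_len(short)]] <- out[ord[seq_len(short)]] + 1L
  }
  out
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# align two sample x type matrices by labels; error on mismatch listing the
# symmetric difference
.alignByLabel <- function(truth, est) {
  truth <- as.matrix(truth)
  est <- as.matrix(est)
  dtypes <- union(setdiff(colnames(truth), colnames(est)),
                  setdiff(colnames(est), colnames(truth)))
  if (length(dtypes)) {
    stop(sprintf("cell-type sets differ between truth and estimate: %s",
                 paste(dtypes, collapse = ", ")), call. = FALSE)
  }
  if (is.null(rownames(truth)) || is.null(rownames(est))) {
    if (nrow(truth) != nrow(est)) {
      stop("sample counts differ and no sample names to align by",
           call. = FALSE)
    }
    rownames(truth) <- rownames(est) <- sprintf("sample%03d",
                                                seq_len(nrow(truth)))
  } else {
    dsamp <- union(setdiff(rownames(truth), rownames(est)),
                   setdiff(rownames(est), rownames(truth)))
    if (length(dsamp)) {
      stop(sprintf("sample sets differ between truth and estimate: %s",
                   paste(dsamp, collapse = ", ")), call. = FALSE)
    }
  }
  list(truth = truth, est = est[rownames(truth), colnames(truth), drop = FALSE])
}

# resolve a solver argument: "nnls", "dwls" or a function(signature, bulk)
.resolveSolver <- function(solver) {
  if (is.function(solver)) return(solver)
  solver <- match.arg(solver, c("nnls", "dwls"))
  switch(solver,
         nnls = nnlsDeconvolve,
         dwls = dwlsDeconvolve)
}
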