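#' Select marker genes by one-vs-rest differential expression
#'
#' For every cell type at the chosen annotation level a Wilcoxon rank-sum
#' test (normal approximation with tie and continuity correction) compares
#' CPM values of the type's cells against all other cells. Genes with a
#' Benjamini-Hochberg adjusted p-value below `pvalCutoff` and a positive
#' log2 fold-change are kept, ranked by fold-change and capped at
#' `maxGenesPerType`; the union over types is returned in the reference's
#' gene order.
#'
#' @param reference a [SingleCellReference-class].
#' @param level annotation resolution.
#' @param pvalCutoff BH-adjusted p-value cutoff (default 0.05).
#' @param maxGenesPerType per-type cap on selected genes.
#' @return character vector of gene ids, with attribute `byType` (the
#'   per-type ranked selections).
#' @export
selectMarkerGenes <- function(reference, level = "fine", pvalCutoff = 0.05,
                              maxGenesPerType = 200) {
  lab <- cellTypeLabels(reference, level)
  types <- sort(unique(lab))
  if (length(types) < 2) {
    stop("marker selection needs at least 2 cell types", call. = FALSE)
  }
  small <- types[table(lab)[types] < 3]
  if (length(small)) {
    stop(sprintf("cell type(s) with fewer than 3 cells: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  cpm <- cpmNormalize(SummarizedExperiment::assay(reference, "counts"))
  x <- as.matrix(cpm)
  n <- ncol(x)

  # per-gene ranks over all cells, plus the tie-correction term
  ranks <- matrix(0, nrow(x), n)
  tieTerm <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    r <- rank(x[g, ])
    ranks[g, ] <- r
    tab <- table(r)
    tie <- as.numeric(tab[tab > 1])
    tieTerm[g] <- sum(tie^3 - tie)
  }

  byType <- stats::setNames(vector("list", length(types)), types)
  meanAll <- rowMeans(x)
  for (t in types) {
    inT <- lab == t
    n1 <- sum(inT); n2 <- n - n1
    R1 <- rowSums(ranks[, inT, drop = FALSE])
    U <- R1 - n1 * (n1 + 1) / 2
    muU <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1))))
    z <- U - muU
    z <- (z - sign(z) * 0.5) / pmax(sigma, .Machine$double.eps)
    p <- 2 * stats::pnorm(-abs(z))
    mT <- rowMeans(x[, inT, drop = FALSE])
    mR <- (meanAll * n - mT * n1) / n2
    lfc <- log2((mT + 1) / (mR + 1))
    padj <- stats::p.adjust(p, method = "BH")
    sel <- which(padj < pvalCutoff & lfc > 0)
    sel <- sel[order(-lfc[sel])]
    if (length(sel) > maxGenesPerType) sel <- sel[seq_len(maxGenesPerType)]
    byType[[t]] <- rownames(x)[sel]
  }
  genes <- rownames(x)[rownames(x) %in% unique(unlist(byType))]
  if (length(genes) == 0) {
    stop("no genes passed marker selection; consider a looser pval_cutoff",
         call. = FALSE)
  }
  attr(genes, "byType") <- byType
  genes
}

#' Build a signature matrix
#'
#' Entry (g, t) is the mean CPM of gene g over the cells of type t at the
#' chosen annotation level, restricted to the supplied gene set. Columns
#' are sorted by type label; genes that are zero in every type are dropped
#' with a message.
#'
#' @param reference a [SingleCellReference-class].
#' @param genes character vector of gene ids (subset of the reference).
#' @param level annotation resolution.
#' @return a [SignatureMatrix-class].
#' @export
buildSignature <- function(reference, genes, level = "fine") {
  unknown <- setdiff(genes, rownames(reference))
  if (length(unknown)) {
    stop(sprintf("unknown gene(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  lab <- cellTypeLabels(reference, level)
  types <- sort(unique(lab))
  cpm <- cpmNormalize(SummarizedExperiment::assay(reference, "counts"))
  ind <- sapply(types, function(t) as.numeric(lab == t) / sum(lab == t))
  vals <- as.matrix(cpm %*% ind)
  colnames(vals) <- types
  vals <- vals[genes, , drop = FALSE]
  zero <- rowSums(vals) == 0
  if (any(zero)) {
    message(sprintf("dropped %d all-zero signature gene(s)", sum(zero)))
    vals <- vals[!zero, , drop = FALSE]
  }
  methods::new("SignatureMatrix", values = vals,
               buildMeta = list(level = level, n_genes = nrow(vals),
                                n_types = ncol(vals)))
}

#' Entropy-based cell-type specificity per gene
#'
#' For gene g with signature row r, let p_t = r_t / sum(r). The score is
#' `1 - H(p) / log2(C)` with Shannon entropy H in bits and C the number of
#' cell types: 1 for a perfectly type-specific (one-hot) gene, 0 for a gene
#' expressed uniformly across types.
#'
#' @param signature a [SignatureMatrix-class] or gene x type matrix.
#' @return named numeric in \[0, 1\], one value per gene.
#' @export
entropySpecificity <- function(signature) {
  v <- if (methods::is(signature, "SignatureMatrix"))
    signatureValues(signature) else as.matrix(signature)
  if (any(rowSums(v) == 0)) stop("all-zero gene row", call. = FALSE)
  C <- ncol(v)
  p <- v / rowSums(v)
  plog <- p * log2(p)
  plog[p == 0] <- 0
  H <- -rowSums(plog)
  stats::setNames(1 - H / log2(C), rownames(v))
}

#' Gini index of a non-negative vector
#'
#' `G = sum_i sum_j |x_i - x_j| / (2 n^2 mean(x))`: 0 when all values are
#' equal, approaching 1 when the mass concentrates on a single entry.
#'
#' @param values non-negative, non-empty numeric vector.
#' @return number in \[0, 1\]; an all-zero vector returns 0 with a warning.
#' @examples
#' giniIndex(c(0, 1))  # 0.5
#' @export
giniIndex <- function(values) {
  if (length(values) == 0) stop("empty vector", call. = FALSE)
  if (any(values < 0)) stop("values must be non-negative", call. = FALSE)
  if (all(values == 0)) {
    warning("all-zero vector: Gini index defined as 0")
    return(0)
  }
  n <- length(values)
  x <- sort(values)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  s <- 2 * sum((2 * seq_len(n) - n - 1) * x)
  s / (2 * n^2 * mean(values))
}

#' Condition number of a signature matrix
#'
#' The ratio of the largest to the smallest singular value, the
#' generalization of `||M|| ||M^-1||` to the rectangular gene x type case.
#' Values near 1 indicate a stable signature; rank-deficient signatures
#' return `Inf` with a diagnostic attribute naming (near-)collinear column
#' pairs.
#'
#' @param signature a [SignatureMatrix-class] or numeric matrix.
#' @return number >= 1, or `Inf` with attribute `collinear`.
#' @export
conditionNumber <- function(signature) {
  m <- if (methods::is(signature, "SignatureMatrix"))
    signatureValues(signature) else as.matrix(signature)
  d <- svd(m, nu = 0, nv = 0)$d
  if (min(d) <= max(d) * .Machine$double.eps * max(dim(m))) {
    cc <- character()
    if (!is.null(colnames(m)) && ncol(m) >= 2) {
      for (a in seq_len(ncol(m) - 1)) {
        for (b in seq(a + 1, ncol(m))) {
          sa <- stats::sd(m[, a]); sb <- stats::sd(m[, b])
          r <- if (sa == 0 || sb == 0) as.numeric(all(m[, a] == m[, b])) else
            stats::cor(m[, a], m[, b])
          if (isTRUE(abs(r) > 1 - 1e-10)) {
            cc <- c(cc, paste(colnames(m)[a], colnames(m)[b], sep = " ~ "))
          }
        }
      }
    }
    out <- Inf
    attr(out, "collinear") <- cc
    return(out)
  }
  max(d) / min(d)
}

#' Signature quality report
#'
#' Per-gene entropy specificity and Gini index, the matrix condition
#' number, and the gene count.
#'
#' @param signature a [SignatureMatrix-class].
#' @return list of class `SignatureQC` with elements `perGene`
#'   (data.frame: gene, entropy_specificity, gini), `conditionNumber` and
#'   `nGenes`.
#' @export
signatureQC <- function(signature) {
  v <- signatureValues(signature)
  structure(list(
    perGene = data.frame(
      gene = rownames(v),
      entropy_specificity = as.numeric(entropySpecificity(signature)),
      gini = apply(v, 1, giniIndex),
      row.names = NULL),
    conditionNumber = conditionNumber(signature),
    nGenes = nrow(v)), class = "SignatureQC")
}
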