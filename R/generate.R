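#' Describe one cell type of a synthetic reference
#'
#' Returns a one-row data.frame; rbind several to form the spec table passed
#' to [generateReference()]. `expressedGeneTarget` is the expected number of
#' nonzero genes per cell and acts as the mRNA-content proxy: cell types
#' that express more genes contribute more mRNA per cell, which is the bias
#' the simulator can re-introduce via scaling factors.
#'
#' @param name unique cell-type label (used as the fine label).
#' @param nCells number of cells (>= 1).
#' @param nMarkers number of exclusive marker genes for this type.
#' @param expressedGeneTarget expected nonzero genes per cell.
#' @param meanLibrarySize expected total counts per cell.
#' @param parentNormal,parentCoarse labels at the two coarser annotation
#'   resolutions; default to `name` (a degenerate hierarchy).
#' @param markerFold mean fold elevation of marker genes over the background.
#' @param shareProfileWith optional name of an earlier spec whose background
#'   expression profile this type copies exactly (only its markers differ);
#'   used to construct controlled-similarity fixtures for spillover studies.
#'   The sharing type must use the same `expressedGeneTarget` and
#'   `meanLibrarySize` as its donor.
#' @return one-row data.frame.
#' @export
cellTypeSpec <- function(name, nCells, nMarkers = 20,
                         expressedGeneTarget = 1000,
                         meanLibrarySize = 20000,
                         parentNormal = name, parentCoarse = name,
                         markerFold = 5, shareProfileWith = NA_character_) {
  stopifnot(length(name) == 1, nCells >= 1, nMarkers >= 0,
            expressedGeneTarget >= 1, meanLibrarySize > 0, markerFold > 0)
  data.frame(name = as.character(name), n_cells = as.integer(nCells),
             n_markers = as.integer(nMarkers),
             expressed_gene_target = as.integer(expressedGeneTarget),
             mean_library_size = as.numeric(meanLibrarySize),
             parent_normal = as.character(parentNormal),
             parent_coarse = as.character(parentCoarse),
             marker_fold = as.numeric(markerFold),
             share_profile_with = as.character(shareProfileWith),
             stringsAsFactors = FALSE)
}

# expected nonzero genes per cell for NB(mu, size): sum_g 1 - P(X_g = 0)
.expectedNonzero <- function(mu, size) {
  sum(1 - (size / (size + mu))^size)
}

# Choose how many background genes a type expresses so the expected nonzero
# gene count per cell hits `target`, given the library size L that the mean
# vector is rescaled to. `markerAbund` and `bgAbund` are relative abundances.
.solveExpressedSet <- function(markerAbund, bgAbund, target, L, size) {
  f <- function(k) {
    ab <- c(markerAbund, bgAbund[seq_len(k)])
    mu <- ab / sum(ab) * L
    .expectedNonzero(mu, size)
  }
  kmax <- length(bgAbund)
  kmin <- max(1L, target - length(markerAbund))
  if (f(kmax) < target) {
    stop(sprintf(paste0("expressed_gene_target %d is unreachable: even with ",
                        "all %d background genes the expected nonzero count ",
                        "is %.0f; increase mean_library_size or n_genes"),
                 target, kmax, f(kmax)), call. = FALSE)
  }
  lo <- min(kmin, kmax)
  if (f(lo) >= target) return(lo)
  hi <- kmax
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

#' Generate an annotated synthetic single-cell reference
#'
#' Counts follow a gamma-Poisson (negative binomial) model with
#' type-specific gene means. Each type expresses its exclusive marker genes
#' (elevated `markerFold`-fold) plus a random subset of a shared background
#' gene pool; the subset size is solved numerically so that the expected
#' number of nonzero genes per cell matches the type's
#' `expressedGeneTarget`, which controls mRNA content. Donor labels are
#' assigned round-robin, mitochondrial fractions are drawn Beta(2, 40), and
#' genes that end up unexpressed in every cell are removed.
#'
#' @param specs data.frame built by rbind-ing [cellTypeSpec()] rows.
#' @param nGenes total number of genes before cleaning.
#' @param nDonors number of donors for round-robin assignment.
#' @param seed integer seed; identical seeds give bit-identical references.
#' @param dispersion negative-binomial size parameter (overdispersion).
#' @param librarySdLog log-normal sd of per-cell library-size factors.
#' @return a [SingleCellReference-class] with planted markers recorded in
#'   `metadata()$markers`.
#' @examples
#' specs <- rbind(
#'   cellTypeSpec("A", 50, nMarkers = 10, expressedGeneTarget = 300,
#'                meanLibrarySize = 3000),
#'   cellTypeSpec("B", 50, nMarkers = 10, expressedGeneTarget = 300,
#'                meanLibrarySize = 3000))
#' ref <- generateReference(specs, nGenes = 1000, nDonors = 2, seed = 1)
#' @export
generateReference <- function(specs, nGenes, nDonors = 3, seed,
                              dispersion = 2, librarySdLog = 0.15) {
  stopifnot(is.data.frame(specs), nrow(specs) >= 1, nGenes >= 1, nDonors >= 1)
  if (anyDuplicated(specs$name)) {
    stop("cell-type names must be unique", call. = FALSE)
  }
  if (any(specs$n_cells < 1)) {
    stop("every cell type needs n_cells >= 1", call. = FALSE)
  }
  if (sum(specs$n_markers) > nGenes) {
    stop(sprintf("marker budget (%d) exceeds n_genes (%d)",
                 sum(specs$n_markers), nGenes), call. = FALSE)
  }
  if (any(specs$expressed_gene_target > nGenes)) {
    stop("expressed_gene_target may not exceed n_genes", call. = FALSE)
  }
  shared <- specs$share_profile_with
  bad <- shared[!is.na(shared) & !shared %in% specs$name]
  if (length(bad)) {
    stop(sprintf("share_profile_with names unknown type(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  geneIds <- sprintf("gene%05d", seq_len(nGenes))
  nTypes <- nrow(specs)

  withr::with_seed(seed, {
    # exclusive marker blocks, then a shared background pool
    markerIdx <- vector("list", nTypes)
    names(markerIdx) <- specs$name
    cursor <- 0L
    for (i in seq_len(nTypes)) {
      nm <- specs$n_markers[i]
      markerIdx[[i]] <- if (nm > 0) cursor + seq_len(nm) else integer()
      cursor <- cursor + nm
    }
    pool <- setdiff(seq_len(nGenes), unlist(markerIdx))

    # per-type mean vectors (length nGenes, zero outside the expressed set)
    muType <- matrix(0, nrow = nGenes, ncol = nTypes)
    bgChoice <- vector("list", nTypes)  # for profile sharing
    bgAbundList <- vector("list", nTypes)
    for (i in seq_len(nTypes)) {
      L <- specs$mean_library_size[i]
      target <- specs$expressed_gene_target[i]
      mk <- markerIdx[[i]]
      markerAbund <- rep(specs$marker_fold[i] * exp(0.5), length(mk))
      if (!is.na(shared[i])) {
        j <- match(shared[i], specs$name)
        if (j >= i) {
          stop("share_profile_with must reference an earlier spec row",
               call. = FALSE)
        }
        bgSel <- bgChoice[[j]]
        bgAb <- bgAbundList[[j]]
      } else {
        ord <- sample(pool)
        ab <- stats::rlnorm(length(ord), meanlog = 0, sdlog = 1)
        k <- .solveExpressedSet(markerAbund, ab, target, L, dispersion)
        bgSel <- ord[seq_len(k)]
        bgAb <- ab[seq_len(k)]
      }
      bgChoice[[i]] <- bgSel
      bgAbundList[[i]] <- bgAb
      abund <- c(markerAbund, bgAb)
      idx <- c(mk, bgSel)
      muType[idx, i] <- abund / sum(abund) * L
    }

    # simulate counts type by type, assembling a sparse matrix
    totalCells <- sum(specs$n_cells)
    triplets <- vector("list", nTypes)
    colOffset <- 0L
    for (i in seq_len(nTypes)) {
      nc <- specs$n_cells[i]
      idx <- which(muType[, i] > 0)
      mu <- muType[idx, i]
      cellFac <- stats::rlnorm(nc, meanlog = -0.5 * librarySdLog^2,
                               sdlog = librarySdLog)
      muMat <- outer(mu, cellFac)
      x <- stats::rnbinom(length(muMat), size = dispersion, mu = as.numeric(muMat))
      nzp <- which(x > 0)
      triplets[[i]] <- list(
        i = idx[(nzp - 1L) %% length(idx) + 1L],
        j = colOffset + ((nzp - 1L) %/% length(idx) + 1L),
        x = x[nzp])
      colOffset <- colOffset + nc
    }
    counts <- Matrix::sparseMatrix(
      i = unlist(lapply(triplets, `[[`, "i")),
      j = unlist(lapply(triplets, `[[`, "j")),
      x = unlist(lapply(triplets, `[[`, "x")),
      dims = c(nGenes, totalCells),
      dimnames = list(geneIds, sprintf("cell%05d", seq_len(totalCells))))

    fine <- rep(specs$name, specs$n_cells)
    ann <- data.frame(
      cell_id = colnames(counts),
      fine = fine,
      normal = specs$parent_normal[match(fine, specs$name)],
      coarse = specs$parent_coarse[match(fine, specs$name)],
      donor_id = sprintf("donor%02d",
                         (seq_len(totalCells) - 1L) %% nDonors + 1L),
      mito_fraction = stats::rbeta(totalCells, 2, 40),
      stringsAsFactors = FALSE)

    # remove genes unexpressed in every cell
    keep <- Matrix::rowSums(counts) > 0
    if (any(!keep)) {
      message(sprintf("removed %d non-expressed gene(s)", sum(!keep)))
      counts <- counts[keep, , drop = FALSE]
    }
    markers <- lapply(markerIdx, function(ii) {
      intersect(geneIds[ii], rownames(counts))
    })
    SingleCellReference(counts, ann, markers = markers)
  })
}
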