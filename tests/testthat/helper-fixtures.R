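# Shared fixtures, built in code at test time. Library sizes are equal
# across types unless a fixture is explicitly about mRNA-content bias, so
# that cell-count fractions and mRNA fractions coincide in the unbiased
# arms.

basicSpecs <- function(nCells = 150) {
  rbind(
    cellTypeSpec("A", nCells, nMarkers = 20, expressedGeneTarget = 800,
                 meanLibrarySize = 5000),
    cellTypeSpec("B", nCells, nMarkers = 20, expressedGeneTarget = 1000,
                 meanLibrarySize = 5000),
    cellTypeSpec("C", nCells, nMarkers = 20, expressedGeneTarget = 1200,
                 meanLibrarySize = 5000))
}

basicRef <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        generateReference(basicSpecs(), nGenes = 3000, nDonors = 3, seed = 1))
    }
    cache
  }
})

# compact specs with targets reachable at ~1000 genes, for I/O-scale tests
smallSpecs <- function(nCells = 40) {
  rbind(
    cellTypeSpec("A", nCells, nMarkers = 10, expressedGeneTarget = 250,
                 meanLibrarySize = 3000),
    cellTypeSpec("B", nCells, nMarkers = 10, expressedGeneTarget = 300,
                 meanLibrarySize = 3000))
}

# types sharing one background profile and differing only in their planted
# markers, so the planted list is the complete ground truth of
# differentially expressed genes
markerOnlySpecs <- function(nCells = 150, nMarkers = 60) {
  rbind(
    cellTypeSpec("A", nCells, nMarkers = nMarkers, expressedGeneTarget = 900,
                 meanLibrarySize = 5000),
    cellTypeSpec("B", nCells, nMarkers = nMarkers, expressedGeneTarget = 900,
                 meanLibrarySize = 5000, shareProfileWith = "A"),
    cellTypeSpec("C", nCells, nMarkers = nMarkers, expressedGeneTarget = 900,
                 meanLibrarySize = 5000, shareProfileWith = "A"))
}

# two types with a 2x expressed-genes spread (equal library size), for
# mRNA-bias direction tests
biasSpecs <- function(nCells = 150) {
  rbind(
    cellTypeSpec("low", nCells, nMarkers = 20, expressedGeneTarget = 700,
                 meanLibrarySize = 6000),
    cellTypeSpec("high", nCells, nMarkers = 20, expressedGeneTarget = 1400,
                 meanLibrarySize = 6000))
}

biasRef <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        generateReference(biasSpecs(), nGenes = 3000, nDonors = 2, seed = 1))
    }
    cache
  }
})

# two near-identical types (shared background profile, own small marker
# sets) plus one distinct type, for spillover / leave-one-out tests
similarSpecs <- function(nCells = 150) {
  rbind(
    cellTypeSpec("S1", nCells, nMarkers = 8, expressedGeneTarget = 900,
                 meanLibrarySize = 5000),
    cellTypeSpec("S2", nCells, nMarkers = 8, expressedGeneTarget = 900,
                 meanLibrarySize = 5000, shareProfileWith = "S1"),
    cellTypeSpec("T", nCells, nMarkers = 40, expressedGeneTarget = 900,
                 meanLibrarySize = 5000))
}

similarRef <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(
        generateReference(similarSpecs(), nGenes = 3000, nDonors = 2,
                          seed = 1))
    }
    cache
  }
})

# a tiny hand-built reference with fully controlled counts
tinyRef <- function(counts, fine, normal = fine, coarse = fine,
                    mito = 0.05) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(n))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  SingleCellReference(counts, data.frame(
    cell_id = colnames(counts), fine = fine, normal = normal,
    coarse = coarse, donor_id = rep("d1", n),
    mito_fraction = rep(mito, length.out = n)))
}

# noiseless / noisy mixtures from a signature: bulk = S f with optional
# multiplicative log-normal noise
mixBulk <- function(signature, truth, noiseSd = 0, seed = 1) {
  S <- signatureValues(signature)
  truth <- truth[, colnames(S), drop = FALSE]
  withr::with_seed(seed, {
    bulk <- sapply(seq_len(nrow(truth)), function(i) {
      v <- as.numeric(S %*% truth[i, ])
      if (noiseSd > 0) v <- v * exp(stats::rnorm(length(v), 0, noiseSd))
      v
    })
  })
  dimnames(bulk) <- list(rownames(S), rownames(truth))
  bulk
}

randomFractionTruth <- function(n, types, seed, floor = 0) {
  withr::with_seed(seed, {
    m <- t(sapply(seq_len(n), function(i) {
      g <- stats::rgamma(length(types), 1)
      g / sum(g)
    }))
  })
  if (floor > 0) m <- (1 - floor * length(types)) * m + floor
  dimnames(m) <- list(sprintf("s%03d", seq_len(n)), types)
  m
}
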