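## benchmark experiments: spillover, unknown content, annotation
## granularity, leave-one-cell-type-out

# signature from a (possibly subsetted) reference: marker selection + mean
# CPM profile
.trainSignature <- function(reference, level, pvalCutoff = 0.05,
                            maxGenesPerType = 200) {
  genes <- selectMarkerGenes(reference, level = level,
                             pvalCutoff = pvalCutoff,
                             maxGenesPerType = maxGenesPerType)
  buildSignature(reference, genes, level = level)
}

#' Spillover experiment on pure pseudo-bulks
#'
#' For every cell type of the simulation reference, simulates `nReps` pure
#' pseudo-bulk replicates (only cells of that type), deconvolves them with
#' a signature trained on `referenceTrain`, and records the mean estimated
#' percentage on the true type (correct %, ideally 100) and on every other
#' type (spill %). The total spillover is the mean over types of
#' (100 - correct %), ideally 0: mass assigned to transcriptionally
#' similar types is the spillover effect.
#'
#' @param referenceSim reference the pure samples are simulated from.
#' @param referenceTrain reference the signature is trained on (may be the
#'   same object).
#' @param solver `"nnls"`, `"dwls"` or a function(signature, bulk) ->
#'   [FractionMatrix-class].
#' @param nReps pure replicates per type.
#' @param nCells cells per pure sample.
#' @param seed integer seed.
#' @param level annotation resolution.
#' @param depth sequencing depth per sample.
#' @param signature optional pre-built [SignatureMatrix-class] (skips
#'   training).
#' @param biasMode bias mode for the simulated samples.
#' @return a [SpilloverReport-class].
#' @export
spilloverExperiment <- function(referenceSim, referenceTrain = referenceSim,
                                solver = "nnls", nReps = 50, nCells = 1000,
                                seed = 1, level = "fine", depth = 1e7,
                                signature = NULL, biasMode = "none") {
  solverFn <- .resolveSolver(solver)
  if (is.null(signature)) {
    signature <- .trainSignature(referenceTrain, level)
  }
  simTypes <- sort(unique(cellTypeLabels(referenceSim, level)))
  missing <- setdiff(simTypes, signatureTypes(signature))
  if (length(missing)) {
    stop(sprintf("simulated type(s) missing from the training signature: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  estTypes <- signatureTypes(signature)
  spill <- matrix(0, length(simTypes), length(estTypes),
                  dimnames = list(simTypes, estTypes))
  for (k in seq_along(simTypes)) {
    cfg <- simulationConfig("pure", nCells = nCells, depth = depth,
                            biasMode = biasMode,
                            seed = seed + (k - 1) * (nReps + 1),
                            pureType = simTypes[k], nReplicates = nReps,
                            level = level)
    ds <- simulateDataset(referenceSim, cfg)
    fm <- solverFn(signature, ds)
    spill[k, ] <- 100 * colMeans(fractions(fm))[estTypes]
  }
  correct <- stats::setNames(spill[cbind(simTypes, simTypes)], simTypes)
  methods::new("SpilloverReport", spillMatrix = spill, correctPct = correct,
               totalSpilloverPct = mean(100 - correct))
}

#' Unknown-content experiment
#'
#' Simulates `weighted_spike` pseudo-bulks with the spike type (e.g. tumor
#' cells) at each requested level, trains a signature on the known types
#' only (each capped at `nCellsSig` cells), deconvolves, and evaluates the
#' known-type estimates against the *unnormalized* ground truth (true
#' known-type mass sums to 1 - level): because sum-to-one solvers must
#' distribute the unknown mass over the known types, estimates at level
#' > 0 are systematically inflated, and the raw comparison quantifies that
#' inflation. A secondary comparison against the renormalized truth is
#' also reported.
#'
#' @param reference a [SingleCellReference-class] containing all types.
#' @param solver solver name or function.
#' @param knownTypes types available for training (spike excluded).
#' @param spikeType the unknown type.
#' @param levels spike fractions in \[0, 1).
#' @param nReplicates technical replicates per level.
#' @param nSamples pseudo-bulk samples per replicate.
#' @param seed integer seed.
#' @param level annotation resolution.
#' @param nCells,depth simulation size per sample.
#' @param nCellsSig per-type cap for the training reference.
#' @return list with per-level results (`raw` and `renormalized`
#'   [EvaluationReport-class]s), `nSamplesTotal`, and the levels.
#' @export
unknownContentExperiment <- function(reference, solver = "nnls", knownTypes,
                                     spikeType,
                                     levels = c(0, 0.05, 0.10, 0.20, 0.30,
                                                0.50, 0.70, 0.80, 0.90),
                                     nReplicates = 5, nSamples = 10, seed = 1,
                                     level = "fine", nCells = 10000,
                                     depth = 1e7, nCellsSig = 500) {
  if (spikeType %in% knownTypes) {
    stop("spikeType must not be among knownTypes", call. = FALSE)
  }
  if (any(levels < 0 | levels >= 1)) {
    stop("spike levels must lie in [0, 1)", call. = FALSE)
  }
  allTypes <- unique(cellTypeLabels(reference, level))
  bad <- setdiff(c(knownTypes, spikeType), allTypes)
  if (length(bad)) {
    stop(sprintf("type(s) not in reference: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  solverFn <- .resolveSolver(solver)

  train <- reference[, cellTypeLabels(reference, level) %in% knownTypes]
  train <- subsampleReference(train, "cap_per_type", nCellsSig,
                              seed = seed, level = level)
  signature <- .trainSignature(train, level)

  results <- vector("list", length(levels))
  names(results) <- sprintf("level_%g", levels)
  nTotal <- 0L
  simTypes <- c(sort(knownTypes), spikeType)
  for (li in seq_along(levels)) {
    truthAll <- NULL; estAll <- NULL
    for (r in seq_len(nReplicates)) {
      cfg <- simulationConfig(
        "weighted_spike", nCells = nCells, depth = depth, biasMode = "none",
        seed = seed + 1000 * (li - 1) + 100 * (r - 1),
        spikeType = spikeType, spikeLevel = levels[li],
        nSamples = nSamples, level = level, types = simTypes)
      ds <- simulateDataset(reference, cfg)
      fm <- solverFn(signature, ds)
      gt <- groundTruth(ds)
      rn <- sprintf("rep%d_%s", r, rownames(gt))
      gt <- gt[, sort(knownTypes), drop = FALSE]
      rownames(gt) <- rn
      ef <- fractions(fm)[, sort(knownTypes), drop = FALSE]
      rownames(ef) <- rn
      truthAll <- rbind(truthAll, gt)
      estAll <- rbind(estAll, ef)
      nTotal <- nTotal + ncol(ds)
    }
    raw <- evaluateFractions(truthAll, estAll)
    renorm <- if (levels[li] > 0) {
      evaluateFractions(truthAll / rowSums(truthAll), estAll)
    } else raw
    results[[li]] <- list(level = levels[li], raw = raw,
                          renormalized = renorm,
                          n_samples = nrow(truthAll))
  }
  list(levels = levels, results = results, nSamplesTotal = nTotal,
       signature = signature)
}

#' Annotation-granularity experiment
#'
#' Simulates `mirror_db` pseudo-bulks at the fine annotation level, then
#' deconvolves them independently with signatures built at each resolution
#' (fine, normal, coarse). Additionally evaluates the aggregation
#' strategy: fine estimates summed to coarse via the reference's label
#' hierarchy, compared to the direct coarse deconvolution.
#'
#' @param reference a [SingleCellReference-class] with a three-level
#'   hierarchy.
#' @param solver solver name or function.
#' @param nReplicates replicate datasets.
#' @param nSamples samples per replicate.
#' @param seed integer seed.
#' @param nCells,depth simulation size per sample.
#' @param nCellsSig per-type cap for training (fine level), `Inf` to skip.
#' @return list with per-level [EvaluationReport-class]s and the
#'   aggregated-fine-to-coarse report.
#' @export
granularityExperiment <- function(reference, solver = "nnls", nReplicates = 5,
                                  nSamples = 10, seed = 1, nCells = 10000,
                                  depth = 1e7, nCellsSig = 500) {
  cd <- SummarizedExperiment::colData(reference)
  for (lv in c("fine", "normal", "coarse")) {
    if (!lv %in% colnames(cd)) {
      stop(sprintf("missing annotation level: %s", lv), call. = FALSE)
    }
  }
  solverFn <- .resolveSolver(solver)
  train <- if (is.finite(nCellsSig)) {
    subsampleReference(reference, "cap_per_type", nCellsSig, seed = seed,
                       level = "fine")
  } else reference

  # simulate once at fine resolution
  datasets <- lapply(seq_len(nReplicates), function(r) {
    cfg <- simulationConfig("mirror_db", nCells = nCells, depth = depth,
                            biasMode = "none", seed = seed + 100 * (r - 1),
                            nSamples = nSamples, level = "fine")
    simulateDataset(reference, cfg)
  })
  truthFine <- do.call(rbind, lapply(seq_along(datasets), function(r) {
    gt <- groundTruth(datasets[[r]])
    rownames(gt) <- sprintf("rep%d_%s", r, rownames(gt))
    gt
  }))
  bulk <- do.call(cbind, lapply(datasets, function(d)
    SummarizedExperiment::assay(d, "counts")))
  colnames(bulk) <- rownames(truthFine)

  perLevel <- list()
  estFine <- NULL
  for (lv in c("fine", "normal", "coarse")) {
    sig <- .trainSignature(train, lv)
    fm <- solverFn(sig, bulk)
    map <- hierarchyMap(reference, "fine", lv)
    truthLv <- fractions(aggregateFractions(truthFine, map))
    perLevel[[lv]] <- evaluateFractions(truthLv, fractions(fm))
    if (lv == "fine") estFine <- fm
  }
  mapFC <- hierarchyMap(reference, "fine", "coarse")
  aggregated <- evaluateFractions(
    fractions(aggregateFractions(truthFine, mapFC)),
    fractions(aggregateFractions(estFine, mapFC)))
  list(perLevel = perLevel, aggregatedCoarse = aggregated,
       truthFine = truthFine)
}

#' Leave-one-cell-type-out experiment
#'
#' For each cell type r of the reference, rebuilds the signature without
#' r's cells, deconvolves the given pseudo-bulks, and reports
#' `deltaRMSE_t = RMSE_t(without r) - RMSE_t(full)` for every remaining
#' type t. Since sum-to-one estimates must redistribute the removed type's
#' mass, positive values show which types absorb it.
#'
#' @param reference training reference.
#' @param solver solver name or function.
#' @param bulk a [PseudoBulkDataset-class] whose truth types are all in the
#'   reference.
#' @param seed integer seed (signature subsampling only, if any).
#' @param level annotation resolution.
#' @return list with `delta` (removed-type x remaining-type matrix, NA on
#'   the diagonal) and `fullReport`.
#' @export
leaveOneOutExperiment <- function(reference, solver = "nnls", bulk,
                                  seed = 1, level = "fine") {
  lab <- cellTypeLabels(reference, level)
  types <- sort(unique(lab))
  if (length(types) < 3) {
    stop("leave-one-out needs at least 3 cell types", call. = FALSE)
  }
  gt <- groundTruth(bulk)
  bad <- setdiff(colnames(gt), types)
  if (length(bad)) {
    stop(sprintf("truth type(s) not in reference: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  solverFn <- .resolveSolver(solver)
  sigFull <- .trainSignature(reference, level)
  fmFull <- solverFn(sigFull, bulk)
  rmseFull <- rmsePerType(gt, fractions(fmFull)[, colnames(gt), drop = FALSE])

  delta <- matrix(NA_real_, length(types), length(types),
                  dimnames = list(removed = types, cell_type = types))
  for (r in types) {
    sub <- reference[, lab != r]
    sigR <- .trainSignature(sub, level)
    fmR <- solverFn(sigR, bulk)
    keep <- setdiff(colnames(gt), r)
    rmseR <- rmsePerType(gt[, keep, drop = FALSE],
                         fractions(fmR)[, keep, drop = FALSE])
    delta[r, keep] <- rmseR - rmseFull[keep]
  }
  list(delta = delta, fullReport = evaluateFractions(
    gt, fractions(fmFull)[, colnames(gt), drop = FALSE]))
}
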