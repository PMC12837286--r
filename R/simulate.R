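#' Per-cell mRNA-content scaling factors
#'
#' In mode `"expressed_genes"` the factor of cell c is its nonzero-gene
#' count divided by the mean nonzero-gene count over all cells (so factors
#' have mean 1); in mode `"none"` all factors are 1. Multiplying each
#' sampled cell's counts by its factor re-introduces the mRNA-content bias
#' present in real bulk samples, where types with more mRNA per cell
#' contribute more reads than their cell-count fraction.
#'
#' @param reference a [SingleCellReference-class].
#' @param mode `"expressed_genes"` or `"none"`.
#' @return a [ScalingFactors-class].
#' @export
computeScalingFactors <- function(reference, mode = c("expressed_genes", "none")) {
  mode <- match.arg(mode)
  if (ncol(reference) == 0) stop("empty reference", call. = FALSE)
  nz <- .colNonzero(SummarizedExperiment::assay(reference, "counts"))
  if (mode == "expressed_genes") {
    if (any(nz == 0)) {
      stop(sprintf("cell(s) with zero expressed genes: %s",
                   paste(names(nz)[nz == 0], collapse = ", ")), call. = FALSE)
    }
    vals <- as.numeric(nz) / mean(nz)
  } else {
    vals <- rep(1, length(nz))
  }
  names(vals) <- colnames(reference)
  methods::new("ScalingFactors", values = vals, mode = mode)
}

#' Integer cell counts per type from target fractions
#'
#' Largest-remainder rounding of `fractions * nCells`, so counts sum exactly
#' to `nCells`. Deterministic: ties in the fractional part are broken by
#' descending fractional part, then label (input) order.
#'
#' @param fractions non-negative named vector summing to 1 (within 1e-9).
#' @param nCells total cells to draw.
#' @param seed ignored (the operation is deterministic); accepted so
#'   callers can treat all sampling steps uniformly.
#' @return named integer vector summing to `nCells`.
#' @examples
#' drawCellCounts(c(A = 1/3, B = 1/3, C = 1/3), 10)  # 4 3 3
#' @export
drawCellCounts <- function(fractions, nCells, seed = NULL) {
  if (any(fractions < 0)) stop("negative fraction", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  stopifnot(nCells >= 1)
  out <- .largestRemainder(fractions, as.integer(nCells))
  names(out) <- names(fractions)
  out
}

#' Pseudo-bulk simulation configuration
#'
#' Scenarios: `mirror_fractions` (user-supplied fraction rows, replicated),
#' `mirror_db` (every sample mirrors the reference's observed type
#' proportions), `random` (per-sample flat-Dirichlet fractions), `pure`
#' (all mass on one type, replicated), and `weighted_spike` (one type fixed
#' at `spikeLevel`, the rest split by a flat Dirichlet) — the scenario used
#' for unknown-content stress tests.
#'
#' @param scenario one of the five scenario names.
#' @param nCells cells sampled (with replacement) per sample; 1,000 for
#'   `pure`, 10,000 otherwise.
#' @param depth total counts per simulated sample.
#' @param biasMode `"expressed_genes"` applies mRNA-content scaling factors;
#'   `"none"` disables them.
#' @param seed integer; per-sample seeds are derived as `seed + index`, so
#'   bias and no-bias runs with the same seed draw identical cells.
#' @param targetFractions samples x type fraction matrix (`mirror_fractions`).
#' @param pureType,spikeType,spikeLevel scenario-specific settings.
#' @param nSamples samples for `mirror_db`, `random`, `weighted_spike`.
#' @param nReplicates replicates for `pure` and per `mirror_fractions` row.
#' @param level annotation resolution the scenario operates on.
#' @param types optional restriction of the simulated type set (default:
#'   all types at `level`).
#' @return a list of class `SimulationConfig`.
#' @export
simulationConfig <- function(scenario = c("mirror_fractions", "mirror_db",
                                          "random", "pure", "weighted_spike"),
                             nCells = NULL, depth = 1e7,
                             biasMode = c("none", "expressed_genes"),
                             seed = 1, targetFractions = NULL,
                             pureType = NULL, spikeType = NULL,
                             spikeLevel = NULL, nSamples = 1,
                             nReplicates = 1, level = "fine", types = NULL) {
  scenario <- match.arg(scenario)
  biasMode <- match.arg(biasMode)
  if (is.null(nCells)) nCells <- if (scenario == "pure") 1000L else 10000L
  stopifnot(nCells >= 1, depth > 0, nSamples >= 1, nReplicates >= 1)
  if (scenario == "mirror_fractions") {
    if (is.null(targetFractions)) {
      stop("mirror_fractions needs targetFractions", call. = FALSE)
    }
    targetFractions <- as.matrix(targetFractions)
    if (any(abs(rowSums(targetFractions) - 1) > 1e-9)) {
      stop("targetFractions rows must sum to 1", call. = FALSE)
    }
  }
  if (scenario == "pure" && is.null(pureType)) {
    stop("pure scenario needs pureType", call. = FALSE)
  }
  if (scenario == "weighted_spike") {
    if (is.null(spikeType) || is.null(spikeLevel)) {
      stop("weighted_spike needs spikeType and spikeLevel", call. = FALSE)
    }
    if (spikeLevel < 0 || spikeLevel >= 1) {
      stop("spikeLevel must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(list(scenario = scenario, nCells = as.integer(nCells),
                 depth = depth, biasMode = biasMode, seed = as.integer(seed),
                 targetFractions = targetFractions, pureType = pureType,
                 spikeType = spikeType, spikeLevel = spikeLevel,
                 nSamples = as.integer(nSamples),
                 nReplicates = as.integer(nReplicates),
                 level = level, types = types),
            class = "SimulationConfig")
}

# draw one pseudo-bulk profile; assumes the RNG state is already set.
# Returns expression (named by gene), truth (cell-count fractions) and the
# per-type drawn counts.
.drawSample <- function(counts, cellsByType, fractions, nCells, depth,
                        factorVals) {
  perType <- drawCellCounts(fractions, nCells)
  weights <- numeric(ncol(counts))
  for (t in names(perType)) {
    k <- perType[[t]]
    if (k == 0) next
    idx <- cellsByType[[t]]
    if (is.null(idx)) {
      stop(sprintf("cell type absent from reference: %s", t), call. = FALSE)
    }
    draw <- idx[sample.int(length(idx), k, replace = TRUE)]
    tab <- tabulate(draw, nbins = ncol(counts))
    weights <- weights + tab
  }
  expr <- as.numeric(counts %*% (weights * factorVals))
  tot <- sum(expr)
  if (tot == 0) stop("simulated sample has zero total counts", call. = FALSE)
  expr <- expr * (depth / tot)
  names(expr) <- rownames(counts)
  list(expression = expr, truth = perType / nCells)
}

#' Simulate one pseudo-bulk sample
#'
#' Samples `nCells` cells with replacement (uniformly within each type, at
#' per-type counts from [drawCellCounts()]), multiplies each drawn cell's
#' counts by its scaling factor, sums, and rescales the aggregate to the
#' requested sequencing depth. The ground truth is recorded as cell-count
#' fractions, **not** mRNA-weighted fractions — with bias enabled the
#' expression and the truth therefore deliberately disagree, which is the
#' mRNA-bias test. Cell draws depend only on (seed, nCells, fractions), not
#' on the bias mode.
#'
#' @param reference a [SingleCellReference-class].
#' @param fractions named target fractions over types at `level`.
#' @param nCells,depth simulation size and sequencing depth.
#' @param factors a [ScalingFactors-class] for the reference.
#' @param seed integer seed.
#' @param level annotation resolution of `fractions`.
#' @return list with `expression` (named numeric over genes) and `truth`
#'   (named cell-count fractions).
#' @export
simulateSample <- function(reference, fractions, nCells, depth, factors,
                           seed, level = "fine") {
  lab <- cellTypeLabels(reference, level)
  missing <- setdiff(names(fractions), unique(lab))
  if (length(missing)) {
    stop(sprintf("cell type(s) absent from reference: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  cellsByType <- split(seq_len(ncol(reference)), lab)
  cnt <- SummarizedExperiment::assay(reference, "counts")
  withr::with_seed(seed, {
    .drawSample(cnt, cellsByType, fractions, nCells, depth,
                factorValues(factors))
  })
}

#' Simulate a pseudo-bulk dataset
#'
#' Runs the scenario in `config` over the derived per-sample seeds
#' (`config$seed + sample index`), so two runs differing only in
#' `biasMode` are exactly paired: they draw the same cells and share the
#' same ground truth, and differ only through the scaling factors.
#'
#' @param reference a [SingleCellReference-class].
#' @param config a [simulationConfig()].
#' @param factors optional [ScalingFactors-class] override; by default
#'   computed from `reference` and `config$biasMode`. Supplying e.g. an
#'   all-ones factor set under any mode supports sensitivity checks of the
#'   bias machinery.
#' @return a [PseudoBulkDataset-class].
#' @export
simulateDataset <- function(reference, config, factors = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  level <- config$level
  lab <- cellTypeLabels(reference, level)
  allTypes <- sort(unique(lab))
  types <- if (is.null(config$types)) allTypes else config$types
  missing <- setdiff(types, allTypes)
  if (length(missing)) {
    stop(sprintf("configured type(s) not in reference: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(factors)) {
    factors <- computeScalingFactors(reference, config$biasMode)
  }
  fv <- factorValues(factors)
  cellsByType <- split(seq_len(ncol(reference)), lab)
  cnt <- SummarizedExperiment::assay(reference, "counts")

  sc <- config$scenario
  if (sc == "mirror_fractions") {
    tf <- config$targetFractions
    bad <- setdiff(colnames(tf), allTypes)
    if (length(bad)) {
      stop(sprintf("mirror_fractions column(s) not in reference: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    targets <- tf[rep(seq_len(nrow(tf)), each = config$nReplicates), ,
                  drop = FALSE]
    nTotal <- nrow(targets)
    truthTypes <- colnames(tf)
  } else if (sc == "pure") {
    if (!config$pureType %in% allTypes) {
      stop(sprintf("pure type not in reference: %s", config$pureType),
           call. = FALSE)
    }
    nTotal <- config$nReplicates
    truthTypes <- types
  } else if (sc == "weighted_spike") {
    if (!config$spikeType %in% allTypes) {
      stop(sprintf("spike type not in reference: %s", config$spikeType),
           call. = FALSE)
    }
    nTotal <- config$nSamples
    truthTypes <- unique(c(setdiff(types, config$spikeType), config$spikeType))
  } else {
    nTotal <- config$nSamples
    truthTypes <- types
  }
  truthTypes <- sort(truthTypes)

  mirrorProps <- NULL
  if (sc == "mirror_db") {
    p <- typeProportions(reference, level)[truthTypes]
    mirrorProps <- p / sum(p)
  }

  expr <- matrix(0, nrow = nrow(reference), ncol = nTotal,
                 dimnames = list(rownames(reference),
                                 sprintf("sample%03d", seq_len(nTotal))))
  truth <- matrix(0, nrow = nTotal, ncol = length(truthTypes),
                  dimnames = list(colnames(expr), truthTypes))
  sampleSeeds <- config$seed + seq_len(nTotal)

  for (i in seq_len(nTotal)) {
    res <- withr::with_seed(sampleSeeds[i], {
      fr <- switch(sc,
        mirror_fractions = {
          v <- as.numeric(targets[i, ]); names(v) <- colnames(targets); v
        },
        mirror_db = mirrorProps,
        random = {
          v <- as.numeric(.rdirichlet(1, rep(1, length(truthTypes))))
          names(v) <- truthTypes; v
        },
        pure = {
          v <- stats::setNames(as.numeric(truthTypes == config$pureType),
                               truthTypes); v
        },
        weighted_spike = {
          others <- setdiff(truthTypes, config$spikeType)
          w <- as.numeric(.rdirichlet(1, rep(1, length(others))))
          v <- stats::setNames(numeric(length(truthTypes)), truthTypes)
          v[others] <- (1 - config$spikeLevel) * w
          v[config$spikeType] <- config$spikeLevel
          v
        })
      .drawSample(cnt, cellsByType, fr, config$nCells, config$depth, fv)
    })
    expr[, i] <- res$expression
    truth[i, names(res$truth)] <- res$truth
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = expr),
    metadata = list(
      ground_truth = truth,
      provenance = list(
        scenario = sc, n_cells = config$nCells, depth = config$depth,
        bias_mode = config$biasMode, factor_mode = factors@mode,
        seed = config$seed, sample_seeds = sampleSeeds, level = level,
        spike_type = config$spikeType, spike_level = config$spikeLevel,
        pure_type = config$pureType)))
  methods::new("PseudoBulkDataset", se)
}
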