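test_that("spillover rows are compositional and orthogonal types barely spill", {
  ref <- basicRef()
  sig <- buildSignature(ref, selectMarkerGenes(ref))
  sp <- spilloverExperiment(ref, ref, solver = "nnls", nReps = 10,
                            nCells = 500, seed = 1, signature = sig)
  expect_equal(unname(rowSums(sp@spillMatrix)), rep(100, 3),
               tolerance = 1e-6)
  expect_lt(sp@totalSpilloverPct, 1)
  expect_true(all(sp@correctPct > 99))
})

test_that("spill concentrates between transcriptionally similar types", {
  ref <- similarRef()
  sp <- spilloverExperiment(ref, ref, solver = "nnls", nReps = 10,
                            nCells = 500, seed = 1)
  sm <- sp@spillMatrix
  # off-diagonal mass of S1 goes to S2, not to the distinct type T
  expect_gt(sm["S1", "S2"], sm["S1", "T"])
  expect_gt(sm["S2", "S1"], sm["S2", "T"])
})

test_that("unknown-content experiment counts samples and degrades gracefully", {
  ref <- suppressMessages(generateReference(rbind(
    basicSpecs(120),
    cellTypeSpec("tumor", 120, nMarkers = 30, expressedGeneTarget = 1000,
                 meanLibrarySize = 5000)), 3000, 2, seed = 1))
  res <- unknownContentExperiment(
    ref, solver = "nnls", knownTypes = c("A", "B", "C"), spikeType = "tumor",
    levels = c(0, 0.3), nReplicates = 2, nSamples = 3, seed = 1,
    nCells = 1000, depth = 1e6, nCellsSig = 100)
  expect_equal(res$nSamplesTotal, 2 * 2 * 3)
  lvl0 <- res$results[[1]]
  # level 0 reduces to a plain evaluation with strong recovery
  expect_gt(as.numeric(globalPearson(lvl0$raw)), 0.95)
  # estimates always sum to 1 while the true known mass is 1 - level
  lvl3 <- res$results[[2]]
  expect_gt(mean(sampleRMSE(lvl3$raw)), mean(sampleRMSE(lvl0$raw)))
})

test_that("granularity experiment evaluates all levels and aggregation", {
  specs <- rbind(
    cellTypeSpec("cd4", 100, 15, 800, 5000, parentNormal = "tcell",
                 parentCoarse = "lymph"),
    cellTypeSpec("cd8", 100, 15, 800, 5000, parentNormal = "tcell",
                 parentCoarse = "lymph"),
    cellTypeSpec("bcell", 100, 15, 900, 5000, parentNormal = "bcell",
                 parentCoarse = "lymph"),
    cellTypeSpec("mono", 100, 15, 1100, 5000, parentNormal = "mono",
                 parentCoarse = "myeloid"))
  ref <- suppressMessages(generateReference(specs, 2500, 2, seed = 1))
  res <- granularityExperiment(ref, solver = "nnls", nReplicates = 1,
                               nSamples = 4, seed = 2, nCells = 1000,
                               depth = 1e6, nCellsSig = Inf)
  expect_named(res$perLevel, c("fine", "normal", "coarse"))
  # aggregated fine truth equals direct coarse truth
  mapFC <- hierarchyMap(ref, "fine", "coarse")
  aggTruth <- fractions(aggregateFractions(res$truthFine, mapFC))
  cfg <- simulationConfig("mirror_db", nCells = 1000, depth = 1e6,
                          seed = 2, nSamples = 4, level = "fine")
  dsCheck <- simulateDataset(ref, cfg)
  directCoarse <- fractions(aggregateFractions(groundTruth(dsCheck), mapFC))
  expect_equal(aggTruth[1:4, ], directCoarse, tolerance = 1e-12,
               ignore_attr = TRUE)
  # mirror_db truth rows identical within a run
  expect_true(all(apply(res$truthFine[1:4, ], 2,
                        function(x) diff(range(x))) < 1e-12))
})

test_that("aggregating a noise-split fine level is at least as good as fine", {
  # two fine types that are exact profile copies under one coarse parent:
  # the fine split is unlearnable, aggregation has to help
  specs <- rbind(
    cellTypeSpec("P1", 120, 0, 900, 5000, parentNormal = "P",
                 parentCoarse = "P"),
    cellTypeSpec("P2", 120, 0, 900, 5000, parentNormal = "P",
                 parentCoarse = "P", shareProfileWith = "P1"),
    cellTypeSpec("Q", 120, 30, 900, 5000, parentNormal = "Q",
                 parentCoarse = "Q"))
  ref <- suppressMessages(generateReference(specs, 2500, 2, seed = 1))
  res <- granularityExperiment(ref, solver = "nnls", nReplicates = 1,
                               nSamples = 5, seed = 3, nCells = 1000,
                               depth = 1e6, nCellsSig = Inf)
  fineP <- perTypeMetrics(res$perLevel$fine)
  aggP <- perTypeMetrics(res$aggregatedCoarse)
  rmseFineP <- mean(fineP$rmse[fineP$cell_type %in% c("P1", "P2")])
  rmseAggP <- aggP$rmse[aggP$cell_type == "P"]
  expect_lte(rmseAggP, rmseFineP + 1e-9)
})

test_that("leave-one-out shifts mass to the similar type", {
  ref <- similarRef()
  cfg <- simulationConfig("random", nCells = 1000, depth = 1e6,
                          seed = 5, nSamples = 8)
  ds <- simulateDataset(ref, cfg)
  res <- leaveOneOutExperiment(ref, solver = "nnls", bulk = ds, seed = 1)
  # removing S1 hurts S2 (it absorbs S1's mass) more than it hurts T
  expect_gt(res$delta["S1", "S2"], 0)
  expect_gt(res$delta["S1", "S2"], abs(res$delta["S1", "T"]))
  expect_true(all(is.na(diag(res$delta))))
  expect_error(
    leaveOneOutExperiment(basicRef()[, cellTypeLabels(basicRef()) != "C"],
                          bulk = ds), "at least 3")
})

test_that("removing a type absent from the bulk barely changes anything", {
  ref <- basicRef()
  # bulk contains only A and B
  tf <- randomFractionTruth(6, c("A", "B"), seed = 9)
  cfg <- simulationConfig("mirror_fractions", nCells = 1000, depth = 1e6,
                          seed = 6, targetFractions = tf, nReplicates = 1)
  ds <- simulateDataset(ref, cfg)
  res <- leaveOneOutExperiment(ref, solver = "nnls", bulk = ds, seed = 1)
  expect_lt(max(abs(res$delta["C", c("A", "B")])), 0.01)
})
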