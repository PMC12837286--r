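test_that("scaling factors follow the expressed-genes rule and have mean 1", {
  cnt <- cbind(c(rep(1, 100), rep(0, 200)), c(rep(1, 300)))
  ref <- tinyRef(cnt, fine = c("A", "B"))
  sf <- computeScalingFactors(ref, "expressed_genes")
  expect_equal(unname(factorValues(sf)), c(0.5, 1.5))
  none <- computeScalingFactors(ref, "none")
  expect_equal(unname(factorValues(none)), c(1, 1))
  # mean-1 invariant on a generated reference
  sf2 <- computeScalingFactors(basicRef(), "expressed_genes")
  expect_equal(mean(factorValues(sf2)), 1, tolerance = 1e-12)
})

test_that("drawCellCounts applies largest-remainder rounding", {
  expect_equal(unname(drawCellCounts(c(a = .5, b = .5), 10)), c(5L, 5L))
  expect_equal(unname(drawCellCounts(c(a = 1, b = 1, c = 1) / 3, 10)),
               c(4L, 3L, 3L))
  expect_error(drawCellCounts(c(a = -0.1, b = 1.1), 10), "negative")
  withr::with_seed(6, {
    for (i in 1:25) {
      k <- sample(2:6, 1)
      f <- rgamma(k, 1); f <- f / sum(f); names(f) <- letters[seq_len(k)]
      n <- sample(1:500, 1)
      cc <- drawCellCounts(f, n)
      expect_equal(sum(cc), n)
      expect_true(all(abs(cc - f * n) < 1))
    }
  })
})

test_that("a pure single-cell sample at native depth returns the cell itself", {
  ref <- basicRef()
  cell <- 7
  lib <- sum(SummarizedExperiment::assay(ref, "counts")[, cell])
  sub <- ref[, cell]  # one-cell reference
  out <- simulateSample(sub, c(A = 1), nCells = 1, depth = lib,
                        factors = computeScalingFactors(sub, "none"),
                        seed = 3)
  expect_equal(out$expression,
               as.numeric(SummarizedExperiment::assay(ref, "counts")[, cell]),
               ignore_attr = TRUE)
  expect_equal(unname(out$truth), 1)
})

test_that("simulated samples conserve sequencing depth", {
  ref <- basicRef()
  cfg <- simulationConfig("random", nCells = 500, depth = 2.5e6,
                          seed = 11, nSamples = 4)
  ds <- simulateDataset(ref, cfg)
  expect_equal(unname(colSums(SummarizedExperiment::assay(ds, "counts"))),
               rep(2.5e6, 4), tolerance = 1e-9)
  expect_equal(unname(rowSums(groundTruth(ds))), rep(1, 4), tolerance = 1e-12)
})

test_that("bias raises the high-mRNA type's share while truth is unchanged", {
  ref <- biasRef()
  tf <- matrix(c(0.5, 0.5), 1, dimnames = list(NULL, c("low", "high")))
  mk <- function(bias) simulationConfig(
    "mirror_fractions", nCells = 2000, depth = 1e6, biasMode = bias,
    seed = 17, targetFractions = tf, nReplicates = 5)
  dsB <- simulateDataset(ref, mk("expressed_genes"))
  dsN <- simulateDataset(ref, mk("none"))
  expect_identical(groundTruth(dsB), groundTruth(dsN))
  # share of counts on the high-content type's markers rises under bias
  mkHigh <- markerGenes(ref)$high
  shareB <- colSums(SummarizedExperiment::assay(dsB, "counts")[mkHigh, ])
  shareN <- colSums(SummarizedExperiment::assay(dsN, "counts")[mkHigh, ])
  expect_true(all(shareB > shareN))
})

test_that("paired arms draw identical cells: unit factors give identical data", {
  ref <- basicRef()
  cfgN <- simulationConfig("random", nCells = 800, depth = 1e6,
                           biasMode = "none", seed = 23, nSamples = 3)
  cfgB <- simulationConfig("random", nCells = 800, depth = 1e6,
                           biasMode = "expressed_genes", seed = 23,
                           nSamples = 3)
  ones <- computeScalingFactors(ref, "none")
  dsN <- simulateDataset(ref, cfgN)
  dsB1 <- simulateDataset(ref, cfgB, factors = ones)
  expect_identical(SummarizedExperiment::assay(dsN, "counts"),
                   SummarizedExperiment::assay(dsB1, "counts"))
  expect_identical(groundTruth(dsN), groundTruth(dsB1))
})

test_that("pure scenario yields one-hot ground truth for every replicate", {
  ref <- basicRef()
  cfg <- simulationConfig("pure", nCells = 1000, depth = 1e6, seed = 2,
                          pureType = "B", nReplicates = 50)
  ds <- simulateDataset(ref, cfg)
  expect_equal(ncol(ds), 50)
  gt <- groundTruth(ds)
  expect_true(all(gt[, "B"] == 1))
  expect_true(all(gt[, c("A", "C")] == 0))
})

test_that("mirror_db repeats the reference's observed proportions", {
  ref <- basicRef()
  cfg <- simulationConfig("mirror_db", nCells = 3000, depth = 1e6,
                          seed = 4, nSamples = 4)
  ds <- simulateDataset(ref, cfg)
  gt <- groundTruth(ds)
  expect_true(all(apply(gt, 2, function(x) diff(range(x))) < 1e-12))
  props <- typeProportions(ref, "fine")
  expect_equal(gt[1, names(props)], props, tolerance = 1e-3)
})

test_that("weighted_spike fixes the spike fraction exactly", {
  ref <- basicRef()
  for (lvl in c(0, 0.5)) {
    cfg <- simulationConfig("weighted_spike", nCells = 1000, depth = 1e6,
                            seed = 8, spikeType = "C", spikeLevel = lvl,
                            nSamples = 5)
    ds <- simulateDataset(ref, cfg)
    expect_equal(unname(groundTruth(ds)[, "C"]), rep(lvl, 5))
  }
})

test_that("scenario misconfiguration is rejected", {
  ref <- basicRef()
  expect_error(simulationConfig("pure"), "pureType")
  expect_error(simulationConfig("weighted_spike", spikeType = "C",
                                spikeLevel = 1), "spikeLevel")
  tf <- matrix(1, 1, dimnames = list(NULL, "nonexistent"))
  cfg <- simulationConfig("mirror_fractions", targetFractions = tf, seed = 1)
  expect_error(simulateDataset(ref, cfg), "nonexistent")
})
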