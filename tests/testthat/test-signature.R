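test_that("marker selection recovers planted markers with high precision", {
  # types share one background profile, so the planted markers are the
  # complete set of truly differential genes
  ref <- suppressMessages(generateReference(markerOnlySpecs(), 3000, 2,
                                            seed = 1))
  genes <- selectMarkerGenes(ref, pvalCutoff = 0.05)
  byType <- attr(genes, "byType")
  planted <- markerGenes(ref)
  for (t in names(planted)) {
    hits <- intersect(byType[[t]], planted[[t]])
    expect_gte(length(hits) / length(planted[[t]]), 0.95)
  }
  # precision over the full selection: planted markers dominate
  precision <- length(intersect(genes, unlist(planted))) / length(genes)
  expect_gte(precision, 0.9)
})

test_that("an impossible p-value cutoff yields the empty-set error", {
  expect_error(selectMarkerGenes(basicRef(), pvalCutoff = 0), "looser")
})

test_that("two seed-split copies of one type yield near-null selection", {
  # same generative profile, no markers: differences are pure noise, so BH
  # at 5% should admit close to nothing
  specs <- rbind(
    cellTypeSpec("X1", 150, nMarkers = 0, expressedGeneTarget = 800,
                 meanLibrarySize = 5000),
    cellTypeSpec("X2", 150, nMarkers = 0, expressedGeneTarget = 800,
                 meanLibrarySize = 5000, shareProfileWith = "X1"))
  ref <- suppressMessages(generateReference(specs, 2500, 2, seed = 1))
  sel <- tryCatch(selectMarkerGenes(ref, pvalCutoff = 0.05),
                  error = function(e) character())
  expect_lte(length(sel), 0.05 * nrow(ref))
})

test_that("the signature holds per-type mean CPM and marker argmax is right", {
  ref <- basicRef()
  genes <- selectMarkerGenes(ref)
  sig <- buildSignature(ref, genes)
  # manual mean-CPM oracle for one type and a few genes
  cpm <- cpmNormalize(SummarizedExperiment::assay(ref, "counts"))
  labs <- cellTypeLabels(ref)
  g <- signatureGenes(sig)[1:5]
  expect_equal(signatureValues(sig)[g, "A"],
               Matrix::rowMeans(cpm[g, labs == "A"]),
               tolerance = 1e-9)
  # each planted marker peaks in its own type's column
  for (t in names(markerGenes(ref))) {
    mk <- intersect(markerGenes(ref)[[t]], signatureGenes(sig))
    peak <- colnames(signatureValues(sig))[
      apply(signatureValues(sig)[mk, , drop = FALSE], 1, which.max)]
    expect_true(all(peak == t))
  }
  expect_error(buildSignature(ref, c(genes[1], "no_such_gene")),
               "no_such_gene")
})

test_that("one-hot reference structure gives a diagonal signature", {
  cnt <- matrix(0, 3, 6)
  cnt[1, 1:2] <- c(10, 20); cnt[2, 3:4] <- c(5, 5); cnt[3, 5:6] <- c(8, 2)
  ref <- tinyRef(cnt, fine = rep(c("A", "B", "C"), each = 2))
  sig <- buildSignature(ref, rownames(SummarizedExperiment::assay(ref)))
  v <- signatureValues(sig)
  expect_true(all(diag(v) == 1e6))
  expect_true(all(v[upper.tri(v) | lower.tri(v)] == 0))
})

test_that("entropy specificity hits its endpoints and hand values", {
  m <- rbind(uniform = c(1, 1, 1), onehot = c(0, 0, 5), mid = c(2, 1, 1))
  colnames(m) <- c("A", "B", "C")
  e <- entropySpecificity(m)
  expect_equal(unname(e["uniform"]), 0)
  expect_equal(unname(e["onehot"]), 1)
  expect_equal(unname(e["mid"]), 1 - 1.5 / log2(3), tolerance = 1e-12)
})

test_that("the Gini index matches the pairwise-difference oracle", {
  expect_equal(giniIndex(c(4, 4, 4)), 0)
  expect_equal(giniIndex(c(0, 1)), 0.5)
  expect_equal(giniIndex(c(0, 0, 1)), 2 / 3)
  oracle <- function(x) {
    n <- length(x)
    sum(outer(x, x, function(a, b) abs(a - b))) / (2 * n^2 * mean(x))
  }
  withr::with_seed(9, {
    for (i in 1:20) {
      x <- rgamma(sample(2:15, 1), 1)
      expect_equal(giniIndex(x), oracle(x), tolerance = 1e-12)
    }
  })
  expect_warning(z <- giniIndex(c(0, 0)), "all-zero")
  expect_equal(z, 0)
})

test_that("condition number is the singular-value ratio with Inf diagnostics", {
  expect_equal(conditionNumber(diag(3)), 1)
  expect_equal(conditionNumber(diag(c(1, 2))), 2)
  m <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(0, 1, 0))
  k <- conditionNumber(m)
  expect_true(is.infinite(k))
  expect_match(attr(k, "collinear"), "a ~ b", all = FALSE)
  # agreement with base kappa on a well-conditioned rectangular case
  withr::with_seed(2, m2 <- matrix(rgamma(40, 2), 10, 4))
  expect_equal(conditionNumber(m2), kappa(m2, exact = TRUE),
               tolerance = 1e-9)
})

test_that("entropy and Gini rank genes identically on two-type signatures", {
  withr::with_seed(13, {
    m <- matrix(rgamma(60, 1.5), 30, 2)
  })
  colnames(m) <- c("A", "B")
  e <- entropySpecificity(m)
  g <- apply(m, 1, giniIndex)
  expect_equal(order(e), order(g))
})

test_that("adding perfectly type-specific genes never worsens conditioning", {
  # one one-hot gene per type adds c^2 I to the cross-product, which
  # shrinks the singular-value ratio for any scale c
  ref <- basicRef()
  sig <- buildSignature(ref, selectMarkerGenes(ref))
  k0 <- conditionNumber(sig)
  v <- signatureValues(sig)
  for (c in c(10, 1e3, 1e5)) {
    v2 <- rbind(v, diag(c, ncol(v)))
    expect_lte(conditionNumber(v2), k0)
  }
})

test_that("a signature from a large subsample tracks the full signature", {
  ref <- basicRef()  # 150 cells/type
  genes <- selectMarkerGenes(ref)
  sigFull <- buildSignature(ref, genes)
  sub <- subsampleReference(ref, "fraction_per_type", 0.7, seed = 31)
  sigSub <- buildSignature(sub, genes)
  shared <- intersect(signatureGenes(sigFull), signatureGenes(sigSub))
  for (t in signatureTypes(sigFull)) {
    expect_gt(cor(signatureValues(sigFull)[shared, t],
                  signatureValues(sigSub)[shared, t]), 0.95)
  }
})
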