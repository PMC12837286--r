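test_that("NNLS recovers exact mixtures and pure samples", {
  ref <- basicRef()
  sig <- buildSignature(ref, selectMarkerGenes(ref))
  S <- signatureValues(sig)[, c("A", "B")]
  S <- S[rowSums(S) > 0, ]
  sig2 <- methods::new("SignatureMatrix", values = S, buildMeta = list())
  truth <- matrix(c(0.3, 0.7), 1, dimnames = list("s1", c("A", "B")))
  bulk <- mixBulk(sig2, truth)
  fm <- nnlsDeconvolve(sig2, bulk)
  expect_equal(fractions(fm)["s1", ], c(A = 0.3, B = 0.7), tolerance = 1e-6)
  # orthogonal two-column signature, bulk equal to column 1
  So <- cbind(A = c(2, 0, 1, 0), B = c(0, 3, 0, 1))
  rownames(So) <- paste0("g", 1:4)
  sigO <- methods::new("SignatureMatrix", values = So, buildMeta = list())
  fmO <- nnlsDeconvolve(sigO, matrix(So[, 1], dimnames = list(rownames(So),
                                                              "p1")))
  expect_equal(unname(fractions(fmO)["p1", ]), c(1, 0), tolerance = 1e-9)
})

test_that("solvers are scale-invariant and permutation-equivariant", {
  ref <- basicRef()
  sig <- buildSignature(ref, selectMarkerGenes(ref))
  truth <- randomFractionTruth(4, signatureTypes(sig), seed = 3)
  bulk <- mixBulk(sig, truth, noiseSd = 0.05, seed = 4)
  f1 <- fractions(nnlsDeconvolve(sig, bulk))
  f2 <- fractions(nnlsDeconvolve(sig, bulk * 37.5))
  expect_equal(f1, f2, tolerance = 1e-9)
  # permute signature columns
  perm <- c("C", "A", "B")
  sigP <- methods::new("SignatureMatrix",
                       values = signatureValues(sig)[, perm],
                       buildMeta = list())
  f3 <- fractions(nnlsDeconvolve(sigP, bulk))
  expect_equal(f3[, colnames(f1)], f1, tolerance = 1e-9)
})

test_that("gene-overlap and degenerate-input guards fire", {
  ref <- basicRef()
  sig <- buildSignature(ref, selectMarkerGenes(ref))
  bulk <- mixBulk(sig, randomFractionTruth(2, signatureTypes(sig), seed = 1))
  few <- bulk[1:4, , drop = FALSE]  # below 2 x 3 types
  expect_error(nnlsDeconvolve(sig, few), "overlap")
  bad <- bulk; bad[, 2] <- 0
  expect_error(nnlsDeconvolve(sig, bad), "all-zero")
})

test_that("DWLS reproduces exact solutions and uniform-weight equality", {
  ref <- basicRef()
  sig <- buildSignature(ref, selectMarkerGenes(ref))
  truth <- randomFractionTruth(3, signatureTypes(sig), seed = 5, floor = 0.05)
  bulk <- mixBulk(sig, truth)
  fm <- dwlsDeconvolve(sig, bulk)
  expect_equal(fractions(fm), truth[, colnames(fractions(fm))],
               tolerance = 1e-4)
  expect_true(all(solverInfo(fm)$converged))
  # uniform signature rows: all weights equal after capping -> NNLS result
  Su <- matrix(1, 10, 3, dimnames = list(paste0("g", 1:10), c("A", "B", "C")))
  sigU <- methods::new("SignatureMatrix", values = Su, buildMeta = list())
  b <- matrix(3, 10, 1, dimnames = list(rownames(Su), "s1"))
  fN <- fractions(nnlsDeconvolve(sigU, b))
  fD <- fractions(dwlsDeconvolve(sigU, b))
  expect_equal(fD, fN, tolerance = 1e-6)
})

test_that("dampened weighting beats NNLS on a noisy rare type", {
  specs <- rbind(
    cellTypeSpec("A", 150, 25, 800, 5000),
    cellTypeSpec("B", 150, 25, 1000, 5000),
    cellTypeSpec("C", 150, 25, 1200, 5000),
    cellTypeSpec("D", 150, 25, 900, 5000),
    cellTypeSpec("rare", 150, 25, 1000, 5000))
  ref <- suppressMessages(generateReference(specs, 3000, 2, seed = 1))
  sig <- buildSignature(ref, rownames(ref))
  types <- signatureTypes(sig)
  n <- 50
  withr::with_seed(1, {
    rest <- t(sapply(seq_len(n), function(i) {
      g <- rgamma(4, 1); 0.98 * g / sum(g)
    }))
  })
  truth <- cbind(rest, rare = 0.02)
  colnames(truth) <- c(setdiff(types, "rare"), "rare")
  rownames(truth) <- sprintf("s%02d", seq_len(n))
  bulk <- mixBulk(sig, truth, noiseSd = 0.1, seed = 1)
  rmseN <- rmsePerType(truth, fractions(nnlsDeconvolve(sig, bulk)))
  rmseD <- rmsePerType(truth, fractions(dwlsDeconvolve(sig, bulk)))
  expect_lt(rmseD[["rare"]], rmseN[["rare"]])
})

test_that("solver output is deterministic", {
  ref <- basicRef()
  sig <- buildSignature(ref, selectMarkerGenes(ref))
  bulk <- mixBulk(sig, randomFractionTruth(3, signatureTypes(sig), seed = 2),
                  noiseSd = 0.1, seed = 2)
  expect_identical(fractions(dwlsDeconvolve(sig, bulk)),
                   fractions(dwlsDeconvolve(sig, bulk)))
})

test_that("fraction normalization is idempotent and scale-free", {
  expect_equal(unname(fractions(normalizeFractions(
    matrix(c(2, 2), 1, dimnames = list("s", c("a", "b")))))), c(0.5, 0.5),
    ignore_attr = TRUE)
  m <- matrix(c(0.1, 0.3, 0.6), 1, dimnames = list("s", c("a", "b", "c")))
  expect_equal(fractions(normalizeFractions(m)), m)
  expect_equal(fractions(normalizeFractions(m * 7)), m)
  bad <- rbind(m, 0)
  rownames(bad) <- c("ok", "empty")
  expect_error(normalizeFractions(bad), "empty")
})

test_that("aggregation preserves row sums and commutes with normalization", {
  map <- c(cd4 = "T", cd8 = "T", treg = "T", b = "B")
  withr::with_seed(8, {
    raw <- matrix(rgamma(20, 1), 5, 4,
                  dimnames = list(sprintf("s%d", 1:5), names(map)))
  })
  agg <- aggregateFractions(raw, map)
  expect_equal(fractions(agg)[, "T"], rowSums(raw[, c("cd4", "cd8", "treg")]))
  expect_equal(rowSums(fractions(agg)), rowSums(raw))
  # identity map
  idm <- stats::setNames(names(map), names(map))
  expect_equal(fractions(aggregateFractions(raw, idm))[, names(map)], raw)
  # commutation with normalization
  a <- fractions(aggregateFractions(normalizeFractions(raw), map))
  b <- fractions(normalizeFractions(aggregateFractions(raw, map)))
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(aggregateFractions(raw, map[-1]), "cd4")
})
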