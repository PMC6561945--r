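test_that("background subtraction matches hand arithmetic and clamps", {
  genes <- c("G1", "G2", "HK1", "HK2", "N1", "N2")
  m <- matrix(c(10, 3, 20, 20, 4, 6), ncol = 1,
              dimnames = list(genes, "S1"))
  x <- PanelCountSet(m, probeClass = c("endogenous", "endogenous",
                                       "housekeeping", "housekeeping",
                                       "negative_control",
                                       "negative_control"))
  out <- backgroundSubtract(x)
  expect_equal(unname(metadata(out)$background), 5)    # mean of {4, 6}
  expect_equal(unname(counts(out)[c("G1", "G2"), 1]), c(5, 0))
  ## control rows untouched
  expect_equal(unname(counts(out)[c("N1", "N2"), 1]), c(4, 6))
  expect_equal(unname(metadata(out)$nClamped), 1)

  ## all negative controls zero -> unchanged
  m0 <- m; m0[c("N1", "N2"), ] <- 0
  x0 <- PanelCountSet(m0, probeClass = probeClass(x))
  expect_equal(counts(backgroundSubtract(x0)), m0)

  ## everything below background -> all-zero endogenous rows, flagged
  mlow <- m; mlow[c("G1", "G2"), ] <- 1
  xlow <- PanelCountSet(mlow, probeClass = probeClass(x))
  outLow <- backgroundSubtract(xlow)
  expect_true(all(counts(outLow)[c("G1", "G2"), ] == 0))
  expect_equal(unname(metadata(outLow)$nClamped), 2)
})

test_that("housekeeping scaling uses geometric means with zero log-sum", {
  genes <- c("G1", "HK1", "HK2", "N1")
  pc <- c("endogenous", "housekeeping", "housekeeping", "negative_control")
  ## housekeeping geometric means 2 and 8 -> G* = 4, factors {2, 0.5}
  m <- matrix(c(10, 1, 4, 1,
                10, 4, 16, 1), ncol = 2,
              dimnames = list(genes, c("S1", "S2")))
  x <- PanelCountSet(m, probeClass = pc)
  out <- housekeepingScale(x)
  f <- metadata(out)$scaleFactors
  expect_equal(unname(f), c(2, 0.5))
  expect_equal(sum(log(f)), 0)
  expect_equal(unname(counts(out)["G1", ]), c(20, 5))

  ## identical housekeeping counts -> all factors 1
  mEq <- m; mEq[c("HK1", "HK2"), ] <- c(3, 5, 3, 5)
  xEq <- PanelCountSet(mEq, probeClass = pc)
  expect_equal(unname(metadata(housekeepingScale(xEq))$scaleFactors),
               c(1, 1))

  ## invariant to housekeeping probe order
  perm <- c("G1", "HK2", "HK1", "N1")
  xPerm <- PanelCountSet(m[perm, ], probeClass = pc[c(1, 3, 2, 4)])
  expect_equal(metadata(housekeepingScale(xPerm))$scaleFactors, f)

  ## zero housekeeping count -> error
  mZero <- m; mZero["HK1", 1] <- 0
  expect_error(housekeepingScale(PanelCountSet(mZero, probeClass = pc)),
               "geometric mean undefined")
})

test_that("quantile normalization matches the sorted-row-mean oracle", {
  m <- cbind(S1 = c(2, 4, 6), S2 = c(1, 3, 5))
  rownames(m) <- paste0("G", 1:3)
  out <- quantileNormalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5, 5.5))

  ## identical columns and single columns are fixed points
  mId <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantileNormalize(mId), mId)
  single <- matrix(c(5, 1, 3), dimnames = list(NULL, "only"))
  expect_equal(quantileNormalize(single), single)

  ## untied random matrices: exact oracle agreement
  set.seed(42)
  for (i in 1:20) {
    r <- matrix(stats::rnorm(60), 12, 5)
    expect_equal(quantileNormalize(r), bruteQuantileNormalize(r))
  }

  ## ties receive the mean of their candidate quantile values
  mt <- cbind(a = c(2, 2, 5), b = c(1, 3, 9))
  ref <- rowMeans(apply(mt, 2, sort))  # (1.5, 2.5, 7)
  out <- quantileNormalize(mt)
  expect_equal(unname(out[, "a"]), c(mean(ref[1:2]), mean(ref[1:2]), ref[3]))
})

test_that("quantile normalization agrees with an established implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(stats::rexp(200), 40, 5)
  expect_equal(quantileNormalize(m),
               unname(limma::normalizeQuantiles(m)),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("log2 transform is exact, monotone and invertible", {
  m <- matrix(c(0, 1, 3, 7), 2, 2)
  expect_equal(log2Transform(m), matrix(c(0, 1, 2, 3), 2, 2))
  set.seed(1)
  r <- matrix(stats::rexp(50), 10, 5)
  lt <- log2Transform(r)
  expect_true(all((r[1, 1] > r[2, 1]) == (lt[1, 1] > lt[2, 1])))
  expect_equal(2^lt - 1, r, tolerance = 1e-9)
  expect_error(log2Transform(matrix(-1)), "non-negative")
})

test_that("the pipeline returns finite endogenous log2 expression", {
  ds <- generateDataset(SyntheticConfig(nEndogenous = 120, seed = 8))
  out <- normalizePipeline(ds$counts)
  m <- exprMatrix(out$expr)
  expect_equal(dim(m), c(120, 16))
  expect_true(all(is.finite(m)))
  expect_identical(rownames(m), endogenousGenes(ds$counts))
  expect_equal(sum(log(out$report$scaleFactors)), 0, tolerance = 1e-12)
})

test_that("scaling one sample's counts only shifts the global log2 level", {
  ## housekeeping scaling absorbs a per-sample factor c up to the global
  ## reference G*, which moves by c^(1/n); relative expression (all
  ## between-gene and between-sample contrasts) is exactly invariant
  ds <- generateDataset(SyntheticConfig(nEndogenous = 100, seed = 6))
  base <- exprMatrix(normalizePipeline(ds$counts)$expr)
  m2 <- counts(ds$counts)
  m2[, 3] <- m2[, 3] * 2
  scaled <- PanelCountSet(m2, probeClass = probeClass(ds$counts),
                          sampleData = ds$annotation)
  out2 <- exprMatrix(normalizePipeline(scaled)$expr)
  ## on the linear (pre-pseudocount) scale the two runs are exact
  ## multiples: the doubled sample moves the housekeeping reference G*
  ## by 2^(1/16), nothing else
  expect_equal(2^out2 - 1, (2^base - 1) * 2^(1 / 16), tolerance = 1e-9)
})

test_that("quantile step is the identity on equal-column matrices", {
  genes <- c("G1", "G2", "HK1", "HK2", "N1")
  m <- matrix(rep(c(40, 10, 20, 20, 0), 2), ncol = 2,
              dimnames = list(genes, c("S1", "S2")))
  x <- PanelCountSet(m, probeClass = c("endogenous", "endogenous",
                                       "housekeeping", "housekeeping",
                                       "negative_control"))
  withQ <- normalizePipeline(x, quantile = TRUE)
  withoutQ <- normalizePipeline(x, quantile = FALSE)
  expect_equal(exprMatrix(withQ$expr), exprMatrix(withoutQ$expr))
})
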