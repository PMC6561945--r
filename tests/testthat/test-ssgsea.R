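test_that("rank transform gives highest rank to highest expression", {
  m <- matrix(c(0.1, 5, 2), ncol = 1,
              dimnames = list(c("a", "b", "c"), "S1"))
  expect_equal(unname(rankTransform(m)[, 1]), c(1L, 3L, 2L))

  inc <- matrix(1:6, ncol = 1, dimnames = list(paste0("g", 1:6), "S"))
  expect_equal(unname(rankTransform(inc)[, 1]), 1:6)

  tied <- matrix(c(2, 2), ncol = 1, dimnames = list(c("g1", "g2"), "S"))
  expect_equal(unname(rankTransform(tied)[, 1]), c(2L, 1L))

  set.seed(3)
  r <- matrix(stats::rnorm(40), 20, 2,
              dimnames = list(paste0("g", 1:20), c("S1", "S2")))
  rk <- rankTransform(r)
  expect_true(all(apply(rk, 2, sort) == 1:20))
})

test_that("singleton top/bottom sets score +/- 2.5 on five genes", {
  ranks <- stats::setNames(5:1, paste0("g", 1:5))
  for (alpha in c(0, 0.25, 1)) {
    expect_equal(enrichmentScore(ranks, "g1", alpha = alpha), 2.5)
    expect_equal(enrichmentScore(ranks, "g5", alpha = alpha), -2.5)
  }
})

test_that("enrichment score equals the brute-force cumulative-sum oracle", {
  set.seed(101)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    genes <- paste0("g", seq_len(n))
    ranks <- stats::setNames(sample(n), genes)
    setSize <- sample(2:(n - 1), 1)
    geneSet <- sample(genes, setSize)
    alpha <- sample(c(0, 0.25, 0.5, 1), 1)
    expect_equal(enrichmentScore(ranks, geneSet, alpha = alpha),
                 bruteSsgseaScore(ranks, geneSet, alpha),
                 tolerance = 1e-12)
  }
})

test_that("score depends on expression only through within-sample ranks", {
  set.seed(5)
  genes <- paste0("g", 1:30)
  expr <- matrix(stats::rnorm(30), ncol = 1, dimnames = list(genes, "S"))
  geneSet <- sample(genes, 8)
  r1 <- rankTransform(expr)[, 1]
  monotone <- exp(expr * 3) + 2        # strictly monotone transform
  r2 <- rankTransform(monotone)[, 1]
  expect_identical(r1, r2)
  expect_equal(enrichmentScore(r1, geneSet), enrichmentScore(r2, geneSet))
})

test_that("reversing ranks negates the unweighted score", {
  # exact antisymmetry holds for the unweighted walk (alpha = 0) and for
  # singleton sets at any alpha; rank^alpha weights break it otherwise
  set.seed(6)
  n <- 25
  genes <- paste0("g", seq_len(n))
  ranks <- stats::setNames(sample(n), genes)
  rev <- stats::setNames(n + 1L - ranks, genes)
  geneSet <- sample(genes, 7)
  expect_equal(enrichmentScore(rev, geneSet, alpha = 0),
               -enrichmentScore(ranks, geneSet, alpha = 0),
               tolerance = 1e-12)
  single <- sample(genes, 1)
  expect_equal(enrichmentScore(rev, single, alpha = 0.25),
               -enrichmentScore(ranks, single, alpha = 0.25),
               tolerance = 1e-12)
})

test_that("degenerate gene sets are rejected", {
  ranks <- stats::setNames(5:1, paste0("g", 1:5))
  expect_error(suppressWarnings(enrichmentScore(ranks, c("x", "y"))),
               "no members present")
  expect_error(enrichmentScore(ranks, paste0("g", 1:5)), "entire panel")
  expect_warning(enrichmentScore(ranks, c("g1", "zz")), "dropped")
})

test_that("ssgseaMatrix applies filters, normalization and permutations", {
  set.seed(11)
  genes <- paste0("g", 1:40)
  m <- matrix(stats::rnorm(120), 40, 3,
              dimnames = list(genes, c("S1", "S2", "S3")))
  sets <- list(A = genes[1:6], B = genes[7:20], tiny = genes[1:2])
  expect_warning(es <- ssgseaMatrix(m, sets), "fewer than 3")
  expect_equal(rownames(es), c("A", "B"))
  expect_equal(ncol(es), 3)
  ## identical expression -> identical scores
  m2 <- cbind(m, S4 = m[, 1])
  es2 <- suppressWarnings(ssgseaMatrix(m2, sets))
  expect_equal(es2[, "S4"], es2[, "S1"])
  ## permuting samples permutes columns only
  esPerm <- suppressWarnings(ssgseaMatrix(m[, c(3, 1, 2)], sets))
  expect_equal(esPerm, es[, c(3, 1, 2)])
  ## global normalization divides by the overall range
  esRaw <- suppressWarnings(ssgseaMatrix(m, sets, normalizeGlobal = FALSE))
  expect_equal(es, esRaw / (max(esRaw) - min(esRaw)))
})

test_that("injected signature up-shift raises the group's mean score", {
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    genes <- paste0("g", 1:100)
    m <- matrix(stats::rnorm(100 * 8, 6), 100, 8,
                dimnames = list(genes, paste0("S", 1:8)))
    sig <- genes[1:12]
    shifted <- paste0("S", 5:8)
    m[sig, shifted] <- m[sig, shifted] + 1.5
    es <- ssgseaMatrix(m, list(SIG = sig))
    if (mean(es[1, shifted]) > mean(es[1, paste0("S", 1:4)]))
      wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("row z-scores use the population standard deviation", {
  m <- matrix(c(1, 3, -1, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("a", "b")))
  z <- zscoreRows(m)
  expect_equal(unname(z["r1", ]), c(-1, 1))
  expect_equal(unname(z["r2", ]), c(-1, 1))     # already standardized
  set.seed(2)
  r <- matrix(stats::rnorm(50), 5, 10)
  zr <- zscoreRows(r)
  expect_equal(unname(rowMeans(zr)), rep(0, 5))
  expect_equal(unname(sqrt(rowMeans(zr^2))), rep(1, 5))
  const <- rbind(flat = rep(2, 4), var = c(1, 2, 3, 4))
  expect_warning(zc <- zscoreRows(const), "constant row")
  expect_equal(unname(zc["flat", ]), rep(0, 4))
})
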