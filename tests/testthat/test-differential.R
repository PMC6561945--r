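test_that("paired t matches the closed form and stats::t.test", {
  ## per-patient differences {1, 2, 3}: t = 2 sqrt(3), df = 2
  pre <- matrix(c(0, 0, 0), 1, dimnames = list("g", paste0("P", 1:3, "_pre")))
  post <- matrix(c(1, 2, 3), 1, dimnames = list("g", paste0("P", 1:3, "_post")))
  m <- cbind(pre, post)
  pairs <- data.frame(pre = colnames(pre), post = colnames(post))
  res <- pairedTTest(m, pairs)
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * stats::pt(-2 * sqrt(3), 2))
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  set.seed(21)
  m <- matrix(stats::rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("g", 1:5),
                              c(paste0("P", 1:4, "_pre"),
                                paste0("P", 1:4, "_post"))))
  pairs <- data.frame(pre = paste0("P", 1:4, "_pre"),
                      post = paste0("P", 1:4, "_post"))
  res <- pairedTTest(m, pairs)
  for (g in rownames(m)) {
    ref <- stats::t.test(m[g, pairs$post], m[g, pairs$pre], paired = TRUE)
    expect_equal(res[g, "t"], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res[g, "p_value"], ref$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate genes are flagged with p = 1, not dropped", {
  m <- matrix(c(1, 2, 1, 2, 1, 2), 1,
              dimnames = list("g", paste0("S", 1:6)))
  pairs <- data.frame(pre = paste0("S", c(1, 3, 5)),
                      post = paste0("S", c(2, 4, 6)))
  res <- pairedTTest(m, pairs)   # post - pre constant = 1
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_error(pairedTTest(m, pairs[1, , drop = FALSE]), ">= 2")

  ## unpaired: zero pooled variance
  m2 <- matrix(c(0, 0, 1, 1), 1, dimnames = list("g", paste0("S", 1:4)))
  res2 <- unpairedTTest(m2, c("S1", "S2"), c("S3", "S4"))
  expect_true(res2$degenerate)
  expect_equal(res2$p_value, 1)
})

test_that("unpaired t supports pooled and Welch variance modes", {
  set.seed(31)
  m <- matrix(stats::rnorm(4 * 7), 4, 7,
              dimnames = list(paste0("g", 1:4), paste0("S", 1:7)))
  a <- paste0("S", 1:2); b <- paste0("S", 3:7)
  pooled <- unpairedTTest(m, a, b, "pooled")
  welch <- unpairedTTest(m, a, b, "welch")
  for (g in rownames(m)) {
    refP <- stats::t.test(m[g, a], m[g, b], var.equal = TRUE)
    refW <- stats::t.test(m[g, a], m[g, b], var.equal = FALSE)
    expect_equal(pooled[g, "p_value"], refP$p.value, tolerance = 1e-12)
    expect_equal(pooled[g, "df"], unname(refP$parameter))
    expect_equal(welch[g, "p_value"], refW$p.value, tolerance = 1e-12)
    expect_equal(welch[g, "df"], unname(refW$parameter), tolerance = 1e-9)
  }
  ## identical groups -> t = 0, p = 1
  mEq <- matrix(rep(c(1, 2, 1, 2), each = 1), 1,
                dimnames = list("g", paste0("S", 1:4)))
  resEq <- unpairedTTest(mEq, c("S1", "S3"), c("S2", "S4"))
  ## groups {1,1} vs {2,2}? no: S1,S3 = 1,1 vs S2,S4 = 2,2 -> different
  mEq2 <- matrix(c(1, 1, 2, 2), 1, dimnames = list("g", paste0("S", 1:4)))
  res0 <- unpairedTTest(mEq2, c("S1", "S3"), c("S2", "S4"))
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)
  expect_error(unpairedTTest(m, "S1", b), ">= 2")
})

test_that("fold changes follow the anti-log2 convention", {
  m <- matrix(c(3, 3, 4, 4, 2, 2, 3, 3), 2,
              dimnames = list(c("g1", "g2"), paste0("S", 1:4)))
  fc <- foldChange(m, c("S1", "S2"), c("S3", "S4"))
  expect_equal(unname(fc["g1"]), 2^(mean(c(3, 4)) - mean(c(2, 3))))
  set.seed(41)
  r <- matrix(stats::rnorm(30), 3, 10,
              dimnames = list(paste0("g", 1:3), paste0("S", 1:10)))
  a <- paste0("S", 1:4); b <- paste0("S", 5:10)
  expect_equal(foldChange(r, a, b) * foldChange(r, b, a),
               stats::setNames(rep(1, 3), paste0("g", 1:3)))
  ## equal means -> FC 1; one-log2 difference -> FC 2
  expect_equal(unname(foldChange(r, a, a)), rep(1, 3))
  expect_equal(unname(foldChange(r + 1, a, b) / foldChange(r, a, b)),
               rep(1, 3), tolerance = 1e-12)
})

test_that("swapping group labels inverts FC and preserves p", {
  set.seed(51)
  m <- matrix(stats::rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("S", 1:10)))
  a <- paste0("S", 1:5); b <- paste0("S", 6:10)
  resAB <- unpairedTTest(m, a, b)
  resBA <- unpairedTTest(m, b, a)
  expect_equal(resAB$p_value, resBA$p_value)
  expect_equal(foldChange(m, a, b), 1 / foldChange(m, b, a))
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bhAdjust(0.03, m = 1), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03), m = 3), rep(0.03, 3))
  set.seed(61)
  for (i in 1:30) {
    n <- sample(1:40, 1)
    p <- stats::runif(n)
    m <- n + sample(0:20, 1)
    expect_equal(bhAdjust(p, m), bruteBH(p, m), tolerance = 1e-12)
  }
  ## q never decreases p and is monotone in p
  p <- stats::runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(stats::runif(10), m = 5), "universe")
})

test_that("DEG selection filters on p and orders by fold change", {
  res <- data.frame(gene = c("a", "b", "c"),
                    p_value = c(0.01, 0.5, 0.04),
                    q_value = c(0.2, 0.9, 0.3),
                    fold_change = c(1.2, 5, 3.0),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  degs <- selectDegs(res)
  expect_equal(degs$gene, c("c", "a"))
  degs2 <- selectDegs(res, fdrCut = 0.25)
  expect_equal(degs2$fdr_pass, c(FALSE, TRUE))
  none <- selectDegs(transform(res, p_value = 0.5))
  expect_equal(nrow(none), 0)
})

test_that("study comparisons resolve groups and exclude the PR", {
  ann <- smallAnnotation(8, response = c("CR", "CR", "PR", rep("NR", 5)))
  paired <- resolveComparison(ann, "paired_post_vs_pre")
  expect_equal(nrow(paired$pairs), 8)         # PR included in paired design
  pre <- resolveComparison(ann, "unpaired_CR_vs_NR_pre")
  expect_setequal(pre$groupA, c("P1_pre", "P2_pre"))
  expect_length(pre$groupB, 5)
  expect_false(any(grepl("P3", c(pre$groupA, pre$groupB))))  # PR excluded
  post <- resolveComparison(ann, "unpaired_CR_vs_NR_post")
  expect_true(all(grepl("_post$", c(post$groupA, post$groupB))))

  set.seed(71)
  m <- matrix(stats::rnorm(5 * 16, 8), 5, 16,
              dimnames = list(paste0("g", 1:5), ann$sample_id))
  res <- runComparison(m, ann, "unpaired_CR_vs_NR_post",
                       categories = list(Cat1 = c("g1", "g2")))
  expect_equal(res$annotation[1], "Cat1")
  expect_equal(res$annotation[3], "")
  expect_true(all(res$q_value >= res$p_value))
  expect_true(all(res$fold_change > 0))
})

test_that("null data produce a calibrated DEG fraction", {
  set.seed(81)
  n <- 400
  ann <- smallAnnotation(8)
  m <- matrix(stats::rnorm(n * 16, 8), n, 16,
              dimnames = list(paste0("g", seq_len(n)), ann$sample_id))
  res <- runComparison(m, ann, "paired_post_vs_pre")
  frac <- mean(res$p_value < 0.05)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})
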