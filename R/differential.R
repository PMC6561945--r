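## Paired and unpaired per-gene t-tests on log2 expression, anti-log2 fold
## changes, Benjamini-Hochberg adjustment and DEG selection. Tests are
## vectorised over genes; zero-variance (degenerate) genes are kept in the
## tables with p = 1 and a flag rather than dropped.

#' Per-gene paired t-test
#'
#' Classical paired t on per-patient (post - pre) log2 differences,
#' two-tailed. Genes whose differences have zero variance are flagged
#' degenerate and given p = 1.
#'
#' @param expr a [PanelExpressionSet-class] or log2 matrix.
#' @param pairs `data.frame` with columns `pre` and `post` holding sample
#'   ids (one row per patient), e.g. from [completePairs()].
#' @return `data.frame` with columns `gene`, `t`, `df`, `p_value`,
#'   `mean_diff`, `degenerate`.
#' @export
pairedTTest <- function(expr, pairs) {
  m <- exprMatrix(expr)
  if (nrow(pairs) < 2) stop("paired t-test needs >= 2 complete pairs")
  miss <- setdiff(c(pairs$pre, pairs$post), colnames(m))
  if (length(miss)) stop("samples absent from the matrix: ",
                         paste(miss, collapse = ", "))
  d <- m[, pairs$post, drop = FALSE] - m[, pairs$pre, drop = FALSE]
  n <- ncol(d)
  mu <- rowMeans(d)
  s <- apply(d, 1, stats::sd)
  degenerate <- s == 0
  tstat <- ifelse(degenerate, NA_real_, mu / (s / sqrt(n)))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df = n - 1))
  data.frame(gene = rownames(m), t = tstat, df = n - 1, p_value = p,
             mean_diff = mu, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = rownames(m))
}

#' Per-gene unpaired two-sample t-test
#'
#' @param expr a [PanelExpressionSet-class] or log2 matrix.
#' @param groupA,groupB character vectors of sample ids (each of size
#'   >= 2).
#' @param varianceMode `"pooled"` (Student, default) or `"welch"`.
#' @return `data.frame` with columns `gene`, `t`, `df`, `p_value`,
#'   `mean_diff` (A - B), `degenerate`.
#' @export
unpairedTTest <- function(expr, groupA, groupB,
                          varianceMode = c("pooled", "welch")) {
  varianceMode <- match.arg(varianceMode)
  m <- exprMatrix(expr)
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs >= 2 samples")
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  miss <- setdiff(c(groupA, groupB), colnames(m))
  if (length(miss)) stop("samples absent from the matrix: ",
                         paste(miss, collapse = ", "))
  a <- m[, groupA, drop = FALSE]
  b <- m[, groupB, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  muA <- rowMeans(a); muB <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (varianceMode == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, nrow(m))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- se == 0 | !is.finite(se)
  tstat <- ifelse(degenerate, NA_real_, (muA - muB) / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(tstat), df = df))
  data.frame(gene = rownames(m), t = tstat, df = df, p_value = p,
             mean_diff = muA - muB, degenerate = degenerate,
             stringsAsFactors = FALSE, row.names = rownames(m))
}

#' Per-gene anti-log2 fold change
#'
#' `FC = 2^(mean log2 in group A - mean log2 in group B)`, so
#' `FC(A,B) * FC(B,A) = 1`.
#'
#' @param expr a [PanelExpressionSet-class] or log2 matrix.
#' @param groupA,groupB non-empty character vectors of sample ids.
#' @return named numeric vector of fold changes.
#' @export
foldChange <- function(expr, groupA, groupB) {
  m <- exprMatrix(expr)
  if (length(groupA) == 0 || length(groupB) == 0)
    stop("groups must be non-empty")
  2^(rowMeans(m[, groupA, drop = FALSE]) -
     rowMeans(m[, groupB, drop = FALSE]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment over a universe of `m` tests:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1. Delegates to
#' `stats::p.adjust(..., n = m)`.
#'
#' @param p p-values in `[0, 1]`.
#' @param m universe size (defaults to `length(p)`; must be >= it).
#' @return numeric vector of q-values, same order as `p`.
#' @export
bhAdjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("universe size m must be >= length(p)")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Resolve a named study comparison from sample annotations
#'
#' The three study designs: `paired_post_vs_pre` (all complete pairs,
#' CR + PR + NR), and the unpaired `CR_vs_NR` contrasts at one timepoint
#' (partial responders excluded).
#'
#' @param annotation validated annotation `data.frame`.
#' @param design one of `"paired_post_vs_pre"`, `"unpaired_CR_vs_NR_pre"`,
#'   `"unpaired_CR_vs_NR_post"`.
#' @return list with `design`, and either `pairs` (paired) or `groupA` /
#'   `groupB` (unpaired; A = CR, B = NR).
#' @export
resolveComparison <- function(annotation,
                              design = c("paired_post_vs_pre",
                                         "unpaired_CR_vs_NR_pre",
                                         "unpaired_CR_vs_NR_post")) {
  design <- match.arg(design)
  if (design == "paired_post_vs_pre") {
    pairs <- completePairs(annotation)
    if (nrow(pairs) < 2) stop("paired design requires >= 2 complete pairs")
    return(list(design = design, pairs = pairs))
  }
  tp <- if (design == "unpaired_CR_vs_NR_pre") "pre" else "post"
  sel <- annotation$timepoint == tp
  groupA <- annotation$sample_id[sel & annotation$response == "CR"]
  groupB <- annotation$sample_id[sel & annotation$response == "NR"]
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("unpaired design requires >= 2 CR and >= 2 NR samples at ", tp)
  list(design = design, groupA = groupA, groupB = groupB)
}

#' Run a differential expression comparison
#'
#' Computes per-gene t-test, BH q-values and anti-log2 fold changes for a
#' named study comparison. For the paired design the fold change is post
#' vs pre; for the unpaired designs CR vs NR.
#'
#' @param expr a [PanelExpressionSet-class] or log2 matrix.
#' @param annotation validated annotation `data.frame`.
#' @param design see [resolveComparison()].
#' @param varianceMode `"pooled"` (default) or `"welch"`, unpaired designs
#'   only.
#' @param bhUniverse BH universe size; default = number of non-degenerate
#'   genes tested in this comparison.
#' @param categories optional named list / [GeneSetCollection-class] of
#'   annotation categories used to fill the `annotation` column.
#' @return `data.frame` (one row per gene): `gene`, `p_value`, `q_value`,
#'   `fold_change`, `direction` (`up`/`down`/`flat`), `annotation`, `t`,
#'   `df`, `degenerate`.
#' @export
runComparison <- function(expr, annotation, design = "paired_post_vs_pre",
                          varianceMode = "pooled", bhUniverse = NULL,
                          categories = NULL) {
  cmp <- resolveComparison(annotation, design)
  if (cmp$design == "paired_post_vs_pre") {
    tt <- pairedTTest(expr, cmp$pairs)
    fc <- foldChange(expr, cmp$pairs$post, cmp$pairs$pre)
  } else {
    tt <- unpairedTTest(expr, cmp$groupA, cmp$groupB,
                        varianceMode = varianceMode)
    fc <- foldChange(expr, cmp$groupA, cmp$groupB)
  }
  if (is.null(bhUniverse)) bhUniverse <- sum(!tt$degenerate)
  q <- rep(NA_real_, nrow(tt))
  q[!tt$degenerate] <- bhAdjust(tt$p_value[!tt$degenerate], m = bhUniverse)
  q[tt$degenerate] <- 1
  ann <- .annotationStrings(tt$gene, categories)
  data.frame(gene = tt$gene, p_value = tt$p_value, q_value = q,
             fold_change = unname(fc[tt$gene]),
             direction = ifelse(fc[tt$gene] > 1, "up",
                                ifelse(fc[tt$gene] < 1, "down", "flat")),
             annotation = ann, t = tt$t, df = tt$df,
             degenerate = tt$degenerate,
             stringsAsFactors = FALSE, row.names = tt$gene)
}

.annotationStrings <- function(genes, categories) {
  if (is.null(categories)) return(rep("", length(genes)))
  if (is(categories, "GeneSetCollection")) categories <- geneSets(categories)
  vapply(genes, function(g) {
    hit <- names(categories)[vapply(categories, function(s) g %in% s, TRUE)]
    paste(hit, collapse = ", ")
  }, "")
}

#' Select differentially expressed genes
#'
#' Genes with `p < pCut`, ordered from high to low fold change. With
#' `fdrCut` set, a `fdr_pass` column marks the subset with
#' `q <= fdrCut`.
#'
#' @param results `data.frame` from [runComparison()].
#' @param pCut two-tailed p-value cutoff (default 0.05).
#' @param fdrCut optional FDR cutoff (e.g. 0.25).
#' @return the selected rows, ordered by `fold_change` descending.
#' @export
selectDegs <- function(results, pCut = 0.05, fdrCut = NULL) {
  sel <- results[results$p_value < pCut & !results$degenerate, ,
                 drop = FALSE]
  sel <- sel[order(-sel$fold_change), , drop = FALSE]
  if (!is.null(fdrCut)) sel$fdr_pass <- sel$q_value <= fdrCut
  sel
}
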