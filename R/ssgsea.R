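## Single-sample gene set enrichment (ssGSEA). Per sample, genes are
## ranked by expression (highest expression = highest rank); the score of
## a set walks the genes in decreasing rank and accumulates the difference
## between the weighted in-set cumulative distribution (weights rank^alpha)
## and the uniform out-of-set cumulative distribution. The score depends on
## expression only through within-sample ranks.

#' Per-sample rank transform
#'
#' Ranks each column so that the highest expression receives the highest
#' rank `n`. Ties are broken by first-occurrence gene order: among tied
#' genes, the earlier row ranks higher.
#'
#' @param expr a [PanelExpressionSet-class] or numeric matrix.
#' @return integer matrix of the same shape; each column is a permutation
#'   of `1..n_genes`.
#' @export
rankTransform <- function(expr) {
  m <- exprMatrix(expr)
  n <- nrow(m)
  out <- matrix(0L, n, ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    ord <- order(-m[, j], seq_len(n))   # decreasing value, stable by row
    out[ord, j] <- seq.int(n, 1L)
  }
  out
}

#' ssGSEA enrichment score for one sample
#'
#' @param sampleRanks integer vector of per-gene ranks (a column of
#'   [rankTransform()]), named by gene.
#' @param geneSet character vector of member symbols; members absent from
#'   the ranking are dropped with a warning.
#' @param alpha rank-weight exponent (>= 0, default 0.25).
#' @return raw enrichment score (positive when members concentrate at top
#'   ranks).
#' @export
enrichmentScore <- function(sampleRanks, geneSet, alpha = 0.25) {
  stopifnot(alpha >= 0)
  genes <- names(sampleRanks)
  if (is.null(genes)) stop("'sampleRanks' must be named by gene")
  present <- intersect(geneSet, genes)
  if (length(present) < length(geneSet))
    warning(length(geneSet) - length(present),
            " gene set member(s) absent from the matrix were dropped")
  if (length(present) == 0)
    stop("gene set has no members present in the panel")
  if (length(present) == length(genes))
    stop("gene set equals the entire panel (empty complement)")
  ord <- order(sampleRanks, decreasing = TRUE)
  inSet <- genes[ord] %in% present
  w <- as.numeric(sampleRanks[ord])^alpha
  w[!inSet] <- 0
  pIn <- cumsum(w) / sum(w)
  pOut <- cumsum(!inSet) / sum(!inSet)
  sum(pIn - pOut)
}

#' ssGSEA enrichment matrix
#'
#' Applies [enrichmentScore()] to every (set, sample) combination. Sets
#' with fewer than `minGenes` members present in the matrix are dropped
#' with a warning. When `normalizeGlobal` is `TRUE` all entries are
#' divided by the range (max - min) over the whole matrix; degenerate
#' single-cell or zero-range matrices skip the normalization.
#'
#' @param expr a [PanelExpressionSet-class] or numeric matrix.
#' @param sets a [GeneSetCollection-class] or named list.
#' @param alpha rank-weight exponent, default 0.25.
#' @param normalizeGlobal divide by the global score range (default
#'   `TRUE`).
#' @param minGenes minimum number of panel-resident members (default 3).
#' @return numeric matrix, sets x samples.
#' @export
ssgseaMatrix <- function(expr, sets, alpha = 0.25, normalizeGlobal = TRUE,
                         minGenes = 3) {
  m <- exprMatrix(expr)
  if (is(sets, "GeneSetCollection")) sets <- geneSets(sets)
  present <- lapply(sets, intersect, x = rownames(m))
  nAbsent <- lengths(sets) - lengths(present)
  if (any(nAbsent > 0))
    warning(sum(nAbsent), " set member(s) absent from the matrix dropped (",
            paste(names(sets)[nAbsent > 0], collapse = ", "), ")")
  keep <- lengths(present) >= minGenes
  if (!all(keep))
    warning(sum(!keep), " set(s) with fewer than ", minGenes,
            " panel genes dropped: ",
            paste(names(sets)[!keep], collapse = ", "))
  if (!any(keep)) stop("no gene set passes the minimum size filter")
  sets <- present[keep]   # already restricted to panel genes
  ranks <- rankTransform(m)
  es <- matrix(NA_real_, length(sets), ncol(m),
               dimnames = list(names(sets), colnames(m)))
  for (j in seq_len(ncol(m))) {
    r <- ranks[, j]
    for (i in seq_along(sets))
      es[i, j] <- suppressWarnings(enrichmentScore(r, sets[[i]], alpha))
  }
  if (normalizeGlobal && length(es) > 1) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  es
}

#' Row-wise z-scores of an enrichment matrix
#'
#' Standardizes each row to mean 0 and population standard deviation 1
#' (divisor `n`, not `n - 1`). Constant rows are emitted as zeros with a
#' warning.
#'
#' @param m numeric matrix (sets x samples).
#' @return matrix of the same shape.
#' @export
zscoreRows <- function(m) {
  m <- as.matrix(m)
  mu <- rowMeans(m)
  sdPop <- sqrt(rowMeans((m - mu)^2))
  zero <- sdPop == 0
  if (any(zero)) {
    warning(sum(zero), " constant row(s) emitted as zeros: ",
            paste(rownames(m)[zero], collapse = ", "))
    sdPop[zero] <- 1
  }
  out <- (m - mu) / sdPop
  out[zero, ] <- 0
  out
}
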