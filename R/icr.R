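## Immunologic Constant of Rejection (ICR): the 20-transcript signature in
## four functional categories, its per-sample score (mean log2 expression),
## and consensus-clustering classification of samples into ICR
## High / Medium / Low.

.ICR_CATEGORIES <- list(
  "CXCR3_CCR5_chemokines" = c("CXCL9", "CXCL10", "CCL5"),
  "Th1_signaling" = c("IFNG", "IL12B", "TBX21", "CD8A", "STAT1", "IRF1",
                      "CD8B"),
  "Effector" = c("GNLY", "PRF1", "GZMA", "GZMB", "GZMH"),
  "Regulatory" = c("CD274", "CTLA4", "FOXP3", "IDO1", "PDCD1"))

#' ICR gene signature
#'
#' The 20 ICR transcripts grouped in four functional categories:
#' CXCR3/CCR5 chemokines, Th1 signaling, effector, and immune-regulatory
#' genes.
#'
#' @return `icrGeneSets()`: a [GeneSetCollection-class] of the four
#'   categories; `icrSignatureGenes()`: the pooled 20-gene character
#'   vector.
#' @export
icrGeneSets <- function() GeneSetCollection(.ICR_CATEGORIES)

#' @rdname icrGeneSets
#' @export
icrSignatureGenes <- function() unname(unlist(.ICR_CATEGORIES))

#' Per-sample ICR score
#'
#' The ICR score of a sample is the mean log2 expression of the ICR genes
#' present in the matrix. Missing signature genes are dropped with a
#' warning; a matrix containing none of them is an error.
#'
#' @param expr a [PanelExpressionSet-class] or log2 matrix.
#' @param genes signature genes (default the 20 ICR transcripts).
#' @return named numeric vector of per-sample scores.
#' @export
icrScore <- function(expr, genes = icrSignatureGenes()) {
  m <- exprMatrix(expr)
  present <- intersect(genes, rownames(m))
  if (length(present) == 0)
    stop("none of the signature genes are present in the matrix")
  if (length(present) < length(genes))
    warning(length(genes) - length(present),
            " signature gene(s) absent from the matrix were dropped")
  colMeans(m[present, , drop = FALSE])
}

#' Consensus clustering by subsampled Ward-linkage clustering
#'
#' For each repetition, a fraction of the samples is drawn without
#' replacement, hierarchically clustered (Ward linkage, `"ward.D2"`, on
#' Euclidean distances) and cut at each k in `2..maxK`. The consensus
#' matrix entry (i, j) is the number of times i and j co-clustered divided
#' by the number of times they were co-sampled. Final assignments at each
#' k come from Ward clustering of `1 - consensus`.
#'
#' @param data numeric matrix, samples x features.
#' @param maxK largest number of clusters scanned (default 7).
#' @param reps subsampling repetitions (default 5000).
#' @param subsampleFraction fraction of samples drawn per repetition
#'   (default 0.8; 1 reduces to deterministic co-membership of a single
#'   Ward clustering).
#' @param seed RNG seed; identical seed gives identical results.
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(data, maxK = 7, reps = 5000,
                             subsampleFraction = 0.8, seed = 1) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < maxK) stop("need at least maxK (", maxK, ") samples, got ", n)
  if (reps < 1) stop("reps must be >= 1")
  if (subsampleFraction <= 0 || subsampleFraction > 1)
    stop("subsampleFraction must be in (0, 1]")
  ids <- rownames(data)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  nSub <- max(2, ceiling(subsampleFraction * n))
  ks <- 2:maxK
  co <- lapply(ks, function(k) matrix(0, n, n))
  names(co) <- paste0("k", ks)
  together <- matrix(0, n, n)
  .withSeed(seed, {
    for (r in seq_len(reps)) {
      idx <- if (nSub == n) seq_len(n) else sort(sample.int(n, nSub))
      hc <- stats::hclust(stats::dist(data[idx, , drop = FALSE]),
                          method = "ward.D2")
      together[idx, idx] <- together[idx, idx] + 1
      for (k in ks) {
        cl <- stats::cutree(hc, k = k)
        same <- outer(cl, cl, `==`) * 1
        key <- paste0("k", k)
        co[[key]][idx, idx] <- co[[key]][idx, idx] + same
      }
    }
  })
  offDiag <- together[upper.tri(together)]
  if (any(offDiag == 0))
    stop("some sample pairs were never co-sampled; increase 'reps'")
  consensus <- lapply(co, function(m) {
    cm <- m / together
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    cm
  })
  assignments <- vector("list", length(ks))
  names(assignments) <- paste0("k", ks)
  for (i in seq_along(ks)) {
    cm <- consensus[[i]]
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "ward.D2")
    assignments[[i]] <- stats::cutree(hc, k = ks[i])
  }
  new("ConsensusResult", consensus = consensus, assignments = assignments,
      sampleIds = ids, maxK = as.integer(maxK), reps = as.integer(reps),
      subsampleFraction = subsampleFraction, seed = as.integer(seed))
}

#' Assign ICR High / Medium / Low class labels
#'
#' Orders the three consensus clusters by the mean z-scored ICR score of
#' their members: the top cluster is labelled `High`, the middle `Medium`,
#' the bottom `Low`. Ties in cluster means are broken by cluster size,
#' then cluster index (with a message). Labels are invariant to a
#' relabeling of the integer cluster ids.
#'
#' @param result a [ConsensusResult-class] (clusters taken at `k`), or an
#'   integer vector of cluster assignments named by sample.
#' @param scores per-sample ICR scores ([icrScore()]); z-scored internally
#'   across samples.
#' @param k number of clusters (default 3, the ICR convention).
#' @return factor of labels (`Low` < `Medium` < `High`), named by sample.
#' @export
assignIcrClasses <- function(result, scores, k = 3) {
  cl <- if (is(result, "ConsensusResult")) clusterAssignments(result, k)
        else result
  if (length(unique(cl)) != k)
    stop("expected exactly ", k, " clusters, got ", length(unique(cl)))
  if (!all(names(cl) %in% names(scores)))
    stop("scores missing for some samples")
  z <- scale(scores[names(cl)])[, 1]
  means <- tapply(z, cl, mean)
  sizes <- tapply(z, cl, length)
  ord <- order(means, sizes, as.numeric(names(means)))
  if (anyDuplicated(signif(means, 12)))
    message("tie in cluster mean ICR z-scores broken by size, then index")
  labelNames <- if (k == 3) c("Low", "Medium", "High")
                else paste0("C", seq_len(k))
  lab <- stats::setNames(labelNames, names(means)[ord])
  out <- factor(lab[as.character(cl)], levels = labelNames, ordered = TRUE)
  names(out) <- names(cl)
  out
}
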