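## Count-to-log2 normalization chain for nCounter-style panels:
## housekeeping scaling -> negative-control background subtraction ->
## quantile normalization -> log2. Each stage is exported on its own; the
## pipeline wires them in the stated order (configurable).

#' Housekeeping normalization
#'
#' Scales each sample by `f_s = G* / G_s`, where `G_s` is the geometric
#' mean of the housekeeping probe counts in sample `s` and `G*` the
#' geometric mean of the `G_s`. The log scale factors therefore sum to
#' zero. All probe classes are scaled.
#'
#' @param x a [PanelCountSet-class] with at least two housekeeping probes,
#'   all with strictly positive counts.
#' @return a [PanelCountSet-class] with scaled counts; the per-sample
#'   factors are stored in `metadata(x)$scaleFactors`.
#' @export
housekeepingScale <- function(x) {
  stopifnot(is(x, "PanelCountSet"))
  hk <- housekeepingGenes(x)
  if (length(hk) < 2)
    stop("housekeeping normalization needs >= 2 housekeeping probes")
  m <- counts(x)
  hkCounts <- m[hk, , drop = FALSE]
  if (any(hkCounts <= 0))
    stop("housekeeping count of 0 encountered; geometric mean undefined")
  logG <- colMeans(log(hkCounts))
  f <- exp(mean(logG) - logG)          # G*/G_s
  out <- sweep(m, 2, f, `*`)
  xOut <- x
  assay(xOut, "counts") <- out
  metadata(xOut)$scaleFactors <- stats::setNames(f, colnames(m))
  xOut
}

#' Negative-control background subtraction
#'
#' For each sample, estimates background from the negative-control probes
#' and subtracts it from the endogenous and housekeeping counts, clamping
#' at zero. Control rows are retained unchanged.
#'
#' @param x a [PanelCountSet-class] with at least one negative-control
#'   probe.
#' @param method `"mean"` (default, mean of negative controls),
#'   `"mean2sd"` (mean + 2 sd, the stricter convention) or `"none"`.
#' @return a [PanelCountSet-class]; `metadata(x)$background` holds the
#'   per-sample estimate and `metadata(x)$nClamped` the per-sample count
#'   of cells clamped at zero.
#' @export
backgroundSubtract <- function(x, method = c("mean", "mean2sd", "none")) {
  stopifnot(is(x, "PanelCountSet"))
  method <- match.arg(method)
  m <- counts(x)
  neg <- negativeControlGenes(x)
  if (length(neg) == 0)
    stop("background subtraction needs >= 1 negative-control probe")
  negM <- m[neg, , drop = FALSE]
  b <- switch(method,
    mean = colMeans(negM),
    mean2sd = colMeans(negM) + 2 * apply(negM, 2, stats::sd),
    none = rep(0, ncol(m)))
  if (length(neg) == 1 && method == "mean2sd")
    stop("'mean2sd' background needs >= 2 negative-control probes")
  target <- probeClass(x) %in% c("endogenous", "housekeeping")
  sub <- sweep(m[target, , drop = FALSE], 2, b, `-`)
  nClamped <- colSums(sub < 0)
  sub[sub < 0] <- 0
  out <- m
  out[target, ] <- sub
  xOut <- x
  assay(xOut, "counts") <- out
  metadata(xOut)$background <- stats::setNames(b, colnames(m))
  metadata(xOut)$nClamped <- stats::setNames(nClamped, colnames(m))
  xOut
}

#' Quantile normalization
#'
#' Forces every column to the same distribution: the per-rank mean of the
#' column-sorted values. Ties within a column receive the mean of the
#' reference values over the tied ranks (the convention of the canonical
#' algorithm). Column means are equalized as a consequence.
#'
#' @param m numeric matrix, genes x samples, no missing values.
#' @return matrix of the same shape and dimnames.
#' @export
quantileNormalize <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty matrix")
  if (any(is.na(m))) stop("missing values are not supported")
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    sorted <- m[o, j]
    vals <- ref
    ## average reference values over runs of tied input values
    r <- rle(sorted)
    if (any(r$lengths > 1)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (i in which(r$lengths > 1))
        vals[starts[i]:ends[i]] <- mean(ref[starts[i]:ends[i]])
    }
    out[o, j] <- vals
  }
  out
}

#' Log2 transform with pseudocount
#'
#' @param m non-negative numeric matrix.
#' @param pseudocount added before taking log2 (default 1, so clamped
#'   zeros map to 0).
#' @return matrix `log2(m + pseudocount)`.
#' @export
log2Transform <- function(m, pseudocount = 1) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("log2 transform requires non-negative input")
  log2(m + pseudocount)
}

#' Full normalization pipeline
#'
#' Runs housekeeping scaling, negative-control background subtraction,
#' quantile normalization (over the endogenous genes that form the output)
#' and log2 transformation, in that order by default. Returns only the
#' endogenous genes.
#'
#' @param x a [PanelCountSet-class].
#' @param order `"housekeeping_first"` (default) or `"background_first"`.
#' @param background background method, see [backgroundSubtract()].
#' @param pseudocount see [log2Transform()].
#' @param quantile logical; apply quantile normalization (default `TRUE`).
#' @return list with `expr` (a [PanelExpressionSet-class], endogenous
#'   genes only, annotation carried over) and `report` (list:
#'   `scaleFactors`, `background`, `nClamped`, `stages`).
#' @export
normalizePipeline <- function(x,
                              order = c("housekeeping_first",
                                        "background_first"),
                              background = "mean", pseudocount = 1,
                              quantile = TRUE) {
  stopifnot(is(x, "PanelCountSet"))
  order <- match.arg(order)
  stages <- character(0)
  if (order == "housekeeping_first") {
    x <- housekeepingScale(x)
    stages <- c(stages, "housekeeping_scale")
    x <- backgroundSubtract(x, method = background)
    stages <- c(stages, paste0("background_subtract:", background))
  } else {
    x <- backgroundSubtract(x, method = background)
    stages <- c(stages, paste0("background_subtract:", background))
    x <- housekeepingScale(x)
    stages <- c(stages, "housekeeping_scale")
  }
  m <- counts(x)[endogenousGenes(x), , drop = FALSE]
  if (quantile) {
    m <- quantileNormalize(m)
    stages <- c(stages, "quantile_normalize")
  }
  m <- log2Transform(m, pseudocount = pseudocount)
  stages <- c(stages, paste0("log2:pseudocount=", pseudocount))
  ann <- sampleAnnotation(x)
  expr <- PanelExpressionSet(m, sampleData = if (ncol(ann)) ann)
  report <- list(scaleFactors = metadata(x)$scaleFactors,
                 background = metadata(x)$background,
                 nClamped = metadata(x)$nClamped,
                 stages = stages)
  list(expr = expr, report = report)
}

#' Wrap an already-normalized matrix as an expression set
#'
#' For data deposited post-normalization: optionally log2-transforms, then
#' validates and wraps. No housekeeping/background/quantile step is
#' applied.
#'
#' @param m numeric matrix, genes x samples.
#' @param log2Applied `TRUE` (default) when the matrix is already on the
#'   log2 scale; when `FALSE` it is log2-transformed with `pseudocount`.
#' @param pseudocount see [log2Transform()].
#' @param sampleData optional annotation `data.frame`.
#' @return a [PanelExpressionSet-class].
#' @export
asNormalizedExpression <- function(m, log2Applied = TRUE, pseudocount = 1,
                                   sampleData = NULL) {
  m <- as.matrix(m)
  if (!log2Applied) m <- log2Transform(m, pseudocount)
  PanelExpressionSet(m, sampleData = sampleData)
}
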