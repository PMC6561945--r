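## Annotation-category over-representation of DEG lists (one-sided
## hypergeometric over the panel background) and the per-signature net
## fold-change percentage statistic shown in dotted heatmaps.

#' Annotation-category enrichment of a DEG list
#'
#' For each category, the upper-tail hypergeometric probability of
#' observing at least the overlap between the DEG list and the category,
#' drawing `|DEGs|` genes from the background. Results are sorted by
#' ascending p-value.
#'
#' @param degs character vector of DEG symbols (must all be in
#'   `background`).
#' @param categories [GeneSetCollection-class] or named list; memberships
#'   outside the background are ignored.
#' @param background character vector of background genes (the endogenous
#'   panel).
#' @return `data.frame`: `category`, `overlap`, `category_size`,
#'   `deg_size`, `background_size`, `p_value`.
#' @export
categoryEnrichment <- function(degs, categories, background) {
  if (is(categories, "GeneSetCollection")) categories <- geneSets(categories)
  stray <- setdiff(degs, background)
  if (length(stray))
    stop("DEG gene(s) absent from the background: ",
         paste(stray, collapse = ", "))
  N <- length(background)
  n <- length(degs)
  rows <- lapply(names(categories), function(nm) {
    cat <- intersect(categories[[nm]], background)
    K <- length(cat)
    k <- length(intersect(degs, cat))
    ## P(X >= k), X ~ Hypergeom(N, K, n); k = 0 gives p = 1
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = nm, overlap = k, category_size = K,
               deg_size = n, background_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$category), , drop = FALSE]
}

#' Per-signature net fold-change percentage
#'
#' For each gene set, computes per-gene anti-log2 fold changes between two
#' sample groups, counts genes up-regulated at least `fcThreshold`-fold
#' and genes down-regulated at least as strongly (FC <= 1/threshold), and
#' reports the net percentage `100 * (n_up - n_down) / n_genes`, with
#' inversely regulated genes cancelling out. Entries with
#' `|net_percent| < displayCut` are flagged `masked` for display; the
#' values themselves are retained.
#'
#' @param expr a [PanelExpressionSet-class] or log2 matrix.
#' @param groupA,groupB character vectors of sample ids (e.g. post and pre
#'   samples of the paired design).
#' @param sets [GeneSetCollection-class] or named list.
#' @param fcThreshold fold-change threshold (> 1, default 1.5).
#' @param displayCut display mask threshold in percent (default 15).
#' @param strict logical; `TRUE` uses strict inequalities (`>` / `<`),
#'   default `FALSE` uses `>=` / `<=`.
#' @return `data.frame`: `signature`, `n_genes`, `n_up`, `n_down`,
#'   `net_percent`, `masked`.
#' @export
signatureChange <- function(expr, groupA, groupB, sets, fcThreshold = 1.5,
                            displayCut = 15, strict = FALSE) {
  if (fcThreshold <= 1) stop("fcThreshold must be > 1")
  m <- exprMatrix(expr)
  if (is(sets, "GeneSetCollection")) sets <- geneSets(sets)
  fc <- foldChange(m, groupA, groupB)
  rows <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]], rownames(m))
    if (length(genes) == 0) return(NULL)
    f <- fc[genes]
    up <- if (strict) sum(f > fcThreshold) else sum(f >= fcThreshold)
    dn <- if (strict) sum(f < 1 / fcThreshold) else sum(f <= 1 / fcThreshold)
    net <- 100 * (up - dn) / length(genes)
    data.frame(signature = nm, n_genes = length(genes), n_up = up,
               n_down = dn, net_percent = net,
               masked = abs(net) < displayCut, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  do.call(rbind, rows)
}
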