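#' @importFrom BiocGenerics counts
NULL

#' @describeIn PanelCountSet-class raw counts matrix.
#' @param object a `PanelCountSet`.
#' @export
setMethod("counts", "PanelCountSet",
          function(object) assay(object, "counts"))

#' Probe classes of a panel
#'
#' @param x a [PanelCountSet-class].
#' @return character vector of probe classes, named by gene.
#' @export
probeClass <- function(x) {
  stats::setNames(as.character(rowData(x)$probeClass), rownames(x))
}

#' Gene ids of a given probe class
#'
#' @param x a [PanelCountSet-class].
#' @name panel-gene-accessors
#' @return character vector of gene ids.
#' @export
endogenousGenes <- function(x) names(which(probeClass(x) == "endogenous"))

#' @rdname panel-gene-accessors
#' @export
housekeepingGenes <- function(x) names(which(probeClass(x) == "housekeeping"))

#' @rdname panel-gene-accessors
#' @export
negativeControlGenes <- function(x)
  names(which(probeClass(x) == "negative_control"))

#' @rdname panel-gene-accessors
#' @export
positiveControlGenes <- function(x)
  names(which(probeClass(x) == "positive_control"))

#' Per-sample annotation of a panel object
#'
#' @param x a [PanelCountSet-class] or [PanelExpressionSet-class].
#' @return `data.frame` of per-sample annotations (may have zero columns).
#' @export
sampleAnnotation <- function(x) {
  as.data.frame(colData(x))
}

#' Annotation categories of a panel as gene sets
#'
#' Inverts the per-gene `categories` column of `rowData` into a named list
#' of category gene vectors.
#'
#' @param x a [PanelCountSet-class] (or any SummarizedExperiment with a
#'   `categories` rowData column).
#' @return named list of character vectors, or `NULL` when no categories
#'   are annotated.
#' @export
geneCategories <- function(x) {
  col <- rowData(x)$categories
  if (is.null(col)) return(NULL)
  lst <- as.list(col)
  cats <- unique(unlist(lst))
  if (length(cats) == 0) return(NULL)
  out <- lapply(cats, function(cat)
    rownames(x)[vapply(lst, function(v) cat %in% v, TRUE)])
  names(out) <- cats
  out
}

#' Extract the log2 expression matrix
#'
#' Accepts a [PanelExpressionSet-class] or a plain numeric matrix, so every
#' statistical entry point can take either.
#'
#' @param x expression container or matrix.
#' @return numeric matrix, genes x samples.
#' @export
exprMatrix <- function(x) {
  if (is(x, "PanelExpressionSet")) return(assay(x, "log2expr"))
  if (is(x, "SummarizedExperiment")) return(assay(x, 1))
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("cannot extract an expression matrix from class ", class(x)[1])
}
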