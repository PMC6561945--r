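#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData
NULL

## probe classes of an nCounter-style panel
PROBE_CLASSES <- c("endogenous", "housekeeping", "negative_control",
                   "positive_control")

#' Panel count container
#'
#' A `PanelCountSet` holds raw (or partially normalized) probe counts from a
#' targeted expression panel as a `SummarizedExperiment` with a single
#' `"counts"` assay. Each probe carries a `probeClass` (`endogenous`,
#' `housekeeping`, `negative_control` or `positive_control`) in `rowData`,
#' and optionally a `categories` `CharacterList` of annotation-category
#' memberships. Sample annotations live in `colData`.
#'
#' @slot .. see `SummarizedExperiment`; the class adds validity constraints
#'   only.
#' @name PanelCountSet-class
#' @aliases PanelCountSet-class
#' @exportClass PanelCountSet
setClass("PanelCountSet", contains = "SummarizedExperiment")

setValidity("PanelCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (!is.numeric(m)) msg <- c(msg, "'counts' must be numeric")
    else {
      if (any(!is.finite(m))) msg <- c(msg, "'counts' must be finite")
      else if (any(m < 0)) msg <- c(msg, "'counts' must be non-negative")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  pc <- rowData(object)$probeClass
  if (is.null(pc))
    msg <- c(msg, "rowData must contain 'probeClass'")
  else {
    if (!all(pc %in% PROBE_CLASSES))
      msg <- c(msg, sprintf("probeClass values must be in {%s}",
                            paste(PROBE_CLASSES, collapse = ", ")))
    if (!any(pc == "endogenous"))
      msg <- c(msg, "panel must contain at least one endogenous gene")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PanelCountSet
#'
#' @param counts numeric matrix, genes x samples, with unique row and column
#'   names.
#' @param probeClass character vector (one per gene) with values among
#'   `endogenous`, `housekeeping`, `negative_control`, `positive_control`.
#' @param categories optional named list mapping annotation-category names to
#'   character vectors of member genes; converted to a per-gene
#'   `CharacterList` column.
#' @param sampleData optional `data.frame` of per-sample annotations
#'   (rownames or a `sample_id` column matching `colnames(counts)`).
#' @return A [PanelCountSet-class] object.
#' @export
PanelCountSet <- function(counts, probeClass, categories = NULL,
                          sampleData = NULL) {
  counts <- as.matrix(counts)
  if (length(probeClass) != nrow(counts))
    stop("'probeClass' must have one entry per gene")
  catCol <- .categoriesToList(rownames(counts), categories)
  rd <- DataFrame(probeClass = as.character(probeClass),
                  categories = catCol, row.names = rownames(counts))
  cd <- .sampleDataFrame(colnames(counts), sampleData)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowData = rd, colData = cd)
  new("PanelCountSet", se)
}

.categoriesToList <- function(genes, categories) {
  out <- vector("list", length(genes))
  names(out) <- genes
  for (i in seq_along(out)) out[[i]] <- character(0)
  if (!is.null(categories)) {
    if (is(categories, "GeneSetCollection")) categories <- geneSets(categories)
    stray <- setdiff(unique(unlist(categories)), genes)
    if (length(stray))
      stop("annotation categories reference genes absent from the panel: ",
           paste(utils::head(stray, 5), collapse = ", "))
    for (cat in names(categories))
      for (g in categories[[cat]])
        out[[g]] <- c(out[[g]], cat)
  }
  CharacterList(out)
}

.sampleDataFrame <- function(samples, sampleData) {
  if (is.null(sampleData))
    return(DataFrame(row.names = samples))
  sd <- as.data.frame(sampleData)
  if (!is.null(sd$sample_id)) rownames(sd) <- sd$sample_id
  if (!all(samples %in% rownames(sd)))
    stop("sampleData does not cover all samples")
  DataFrame(sd[samples, , drop = FALSE])
}

#' Normalized expression container
#'
#' A `PanelExpressionSet` holds log2-scale normalized expression as a
#' `SummarizedExperiment` with a single `"log2expr"` assay; all values must
#' be finite and ids unique. It is the substrate of every downstream
#' statistic (ssGSEA, ICR scoring, differential expression).
#'
#' @name PanelExpressionSet-class
#' @exportClass PanelExpressionSet
setClass("PanelExpressionSet", contains = "SummarizedExperiment")

setValidity("PanelExpressionSet", function(object) {
  msg <- character()
  if (!"log2expr" %in% assayNames(object))
    msg <- c(msg, "assay 'log2expr' is required")
  else if (any(!is.finite(assay(object, "log2expr"))))
    msg <- c(msg, "'log2expr' must be finite")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PanelExpressionSet
#'
#' @param values numeric matrix of log2 expression, genes x samples, finite,
#'   with unique dimnames.
#' @param sampleData optional per-sample annotation `data.frame`.
#' @param rowData optional `DataFrame` of per-gene metadata.
#' @return A [PanelExpressionSet-class] object.
#' @export
PanelExpressionSet <- function(values, sampleData = NULL, rowData = NULL) {
  values <- as.matrix(values)
  cd <- .sampleDataFrame(colnames(values), sampleData)
  args <- list(assays = list(log2expr = values), colData = cd)
  if (!is.null(rowData)) args$rowData <- rowData
  new("PanelExpressionSet", do.call(SummarizedExperiment, args))
}

#' Named collection of gene sets
#'
#' Simple validated container for named gene lists (ICR categories,
#' leukocyte signatures, panel annotation categories): no empty set, unique
#' set names, unique symbols within each set, member order preserved.
#'
#' @slot sets named list of character vectors.
#' @name GeneSetCollection-class
#' @exportClass GeneSetCollection
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  msg <- character()
  if (length(s) == 0) msg <- c(msg, "collection must contain at least one set")
  if (is.null(names(s)) || any(names(s) == "") || anyDuplicated(names(s)))
    msg <- c(msg, "set names must be present and unique")
  if (any(lengths(s) == 0)) msg <- c(msg, "empty gene sets are not allowed")
  if (any(vapply(s, anyDuplicated, 0L) > 0))
    msg <- c(msg, "within-set gene symbols must be unique")
  if (!all(vapply(s, is.character, TRUE)))
    msg <- c(msg, "sets must be character vectors")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors of gene symbols.
#' @return A `GeneSetCollection`.
#' @export
GeneSetCollection <- function(sets) new("GeneSetCollection", sets = sets)

#' @describeIn GeneSetCollection-class the underlying named list.
#' @param x a `GeneSetCollection`.
#' @export
geneSets <- function(x) x@sets

setMethod("length", "GeneSetCollection", function(x) length(x@sets))
setMethod("names", "GeneSetCollection", function(x) names(x@sets))
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  sizes <- lengths(object@sets)
  cat("  sizes:", min(sizes), "-", max(sizes), "genes\n")
  shown <- utils::head(names(object@sets), 5)
  cat("  names:", paste(shown, collapse = ", "),
      if (length(object@sets) > 5) "..." else "", "\n")
})

#' Synthetic dataset configuration
#'
#' Parameters of the paired-design panel-count generator. Defaults mirror an
#' 8-patient imiquimod-style trial (2 complete responders, 1 partial
#' responder, 5 non-responders, pre/post biopsy per patient) profiled on a
#' 770-gene immune panel: negative-binomial counts with lognormal per-gene
#' baselines, lognormal library-size factors, an ICR up-shift in responder
#' post-treatment samples and a baseline antigen-presentation up-shift in
#' complete-responder samples.
#'
#' @slot nPatients number of patients (two samples each).
#' @slot nCR,nPR number of complete and partial responders; the rest are NR.
#' @slot nEndogenous,nHousekeeping,nNegativeControls,nPositiveControls probe
#'   counts by class.
#' @slot baselineLogMean,baselineLogSd natural-log mean/sd of the lognormal
#'   endogenous gene baselines (counts scale).
#' @slot nbDispersion negative-binomial size parameter (variance =
#'   mu + mu^2/size).
#' @slot icrPostEffectLog2 log2 shift applied to ICR genes in responder
#'   (CR + PR) post-treatment samples.
#' @slot baselineResponderEffectLog2 log2 shift applied to the designated
#'   antigen-presentation gene set in CR pre AND post samples.
#' @slot librarySizeCv coefficient of variation of lognormal per-sample
#'   library factors.
#' @slot seed RNG seed; identical seed gives bitwise-identical output.
#' @name SyntheticConfig-class
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nPatients = "integer", nCR = "integer", nPR = "integer",
                 nEndogenous = "integer", nHousekeeping = "integer",
                 nNegativeControls = "integer", nPositiveControls = "integer",
                 baselineLogMean = "numeric", baselineLogSd = "numeric",
                 nbDispersion = "numeric", icrPostEffectLog2 = "numeric",
                 baselineResponderEffectLog2 = "numeric",
                 librarySizeCv = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nCR + object@nPR > object@nPatients)
    msg <- c(msg, "responders (CR + PR) cannot exceed nPatients")
  if (object@nPatients < 1) msg <- c(msg, "need at least one patient")
  if (object@nEndogenous < 20)
    msg <- c(msg, "need at least 20 endogenous genes (the ICR signature)")
  if (object@nHousekeeping < 2)
    msg <- c(msg, "need at least two housekeeping probes")
  if (object@nNegativeControls < 1)
    msg <- c(msg, "need at least one negative-control probe")
  if (object@baselineLogSd <= 0) msg <- c(msg, "baselineLogSd must be > 0")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  if (object@librarySizeCv < 0) msg <- c(msg, "librarySizeCv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticConfig-class
#' @param nPatients,nCR,nPR,nEndogenous,nHousekeeping,nNegativeControls,nPositiveControls
#'   see slots.
#' @param baselineLogMean,baselineLogSd,nbDispersion,icrPostEffectLog2,baselineResponderEffectLog2,librarySizeCv,seed
#'   see slots.
#' @return A `SyntheticConfig`.
#' @export
SyntheticConfig <- function(nPatients = 8L, nCR = 2L, nPR = 1L,
                            nEndogenous = 770L, nHousekeeping = 40L,
                            nNegativeControls = 8L, nPositiveControls = 6L,
                            baselineLogMean = 5, baselineLogSd = 1.2,
                            nbDispersion = 10, icrPostEffectLog2 = 2,
                            baselineResponderEffectLog2 = 1,
                            librarySizeCv = 0.1, seed = 1L) {
  new("SyntheticConfig",
      nPatients = as.integer(nPatients), nCR = as.integer(nCR),
      nPR = as.integer(nPR), nEndogenous = as.integer(nEndogenous),
      nHousekeeping = as.integer(nHousekeeping),
      nNegativeControls = as.integer(nNegativeControls),
      nPositiveControls = as.integer(nPositiveControls),
      baselineLogMean = baselineLogMean, baselineLogSd = baselineLogSd,
      nbDispersion = nbDispersion, icrPostEffectLog2 = icrPostEffectLog2,
      baselineResponderEffectLog2 = baselineResponderEffectLog2,
      librarySizeCv = librarySizeCv, seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:", object@nPatients, "patients (",
      object@nCR, "CR /", object@nPR, "PR /",
      object@nPatients - object@nCR - object@nPR, "NR ),",
      object@nEndogenous, "endogenous genes\n")
  cat("  ICR post effect:", object@icrPostEffectLog2, "log2;",
      "baseline CR effect:", object@baselineResponderEffectLog2, "log2;",
      "seed:", object@seed, "\n")
})

#' Consensus clustering result
#'
#' Holds, for each k in 2..maxK, the consensus (co-clustering) matrix over
#' subsampled Ward-linkage clusterings, plus per-k final assignments from
#' Ward clustering of 1 - consensus.
#'
#' @slot consensus named list (`k2`, `k3`, ...) of samples x samples
#'   matrices in [0, 1], symmetric with unit diagonal.
#' @slot assignments named list of integer cluster assignments per k.
#' @slot sampleIds character vector of sample ids.
#' @slot maxK,reps,subsampleFraction,seed run parameters.
#' @name ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(consensus = "list", assignments = "list",
                 sampleIds = "character", maxK = "integer", reps = "integer",
                 subsampleFraction = "numeric", seed = "integer"))

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (m in object@consensus) {
    if (any(m < -1e-12) || any(m > 1 + 1e-12))
      msg <- c(msg, "consensus entries must lie in [0, 1]")
    if (max(abs(m - t(m))) > 1e-12)
      msg <- c(msg, "consensus matrices must be symmetric")
    if (max(abs(diag(m) - 1)) > 1e-12)
      msg <- c(msg, "consensus diagonal must be 1")
  }
  if (length(msg)) unique(msg) else TRUE
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult:", length(object@sampleIds), "samples, k = 2..",
      object@maxK, ", ", object@reps, " subsampling repetitions (fraction ",
      object@subsampleFraction, ")\n", sep = "")
})

#' @describeIn ConsensusResult-class consensus matrix at a given k.
#' @param x a `ConsensusResult`.
#' @param k number of clusters.
#' @export
consensusMatrix <- function(x, k) {
  stopifnot(is(x, "ConsensusResult"))
  x@consensus[[paste0("k", k)]]
}

#' @describeIn ConsensusResult-class integer cluster assignments at a given k.
#' @export
clusterAssignments <- function(x, k) {
  stopifnot(is(x, "ConsensusResult"))
  a <- x@assignments[[paste0("k", k)]]
  names(a) <- x@sampleIds
  a
}
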