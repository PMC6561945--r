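## Orchestration: normalize -> ssGSEA -> ICR scoring/classification ->
## differential expression -> category enrichment -> enrichment-score fold
## changes -> PCA, over the study's three standard comparisons, collected
## into a single report bundle.

#' Principal component analysis of samples
#'
#' Genes are centered (no scaling) and the centered matrix decomposed by
#' SVD (`stats::prcomp` with samples as observations). Components are
#' ordered by explained variance; each component's sign is fixed so that
#' its largest-magnitude gene loading is positive.
#'
#' @param expr a [PanelExpressionSet-class] or log2 matrix.
#' @param nComponents number of components to return (default 3).
#' @return list with `coordinates` (samples x components), `loadings`
#'   (genes x components), `varianceExplained` (fractions, non-increasing).
#' @export
runPCA <- function(expr, nComponents = 3) {
  m <- exprMatrix(expr)
  if (ncol(m) < 2) stop("PCA needs >= 2 samples")
  if (all(apply(m, 1, stats::var) == 0))
    stop("constant matrix has zero variance")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                     # sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = scores, loadings = rot,
       varianceExplained = varFrac[seq_len(k)])
}

STUDY_DESIGNS <- c("paired_post_vs_pre", "unpaired_CR_vs_NR_pre",
                   "unpaired_CR_vs_NR_post")

#' Run the full panel analysis
#'
#' Executes every stage on a count set (or directly on a pre-normalized
#' expression set): normalization, ssGSEA of the supplied signatures plus
#' the pooled ICR set, ICR scoring and consensus classification,
#' differential expression over the requested comparisons, DEG selection
#' and category enrichment, enrichment-score fold changes, and PCA.
#' Comparison stages that cannot be resolved (e.g. no post samples for the
#' paired design) are recorded as error strings without aborting the
#' others. Reruns with identical inputs and seed are reproducible.
#'
#' @param counts a [PanelCountSet-class], or `NULL` when `expr` is given.
#' @param expr optional pre-normalized [PanelExpressionSet-class] (used
#'   as-is; normalization is skipped).
#' @param annotation validated annotation `data.frame`; defaults to the
#'   annotation carried in `counts`/`expr`.
#' @param signatures [GeneSetCollection-class] / named list of leukocyte
#'   signatures for ssGSEA.
#' @param categories optional annotation categories for enrichment;
#'   defaults to the categories annotated on `counts`.
#' @param comparisons character vector of designs (default the study's
#'   three).
#' @param pCut DEG p-value cutoff (default 0.05).
#' @param fdrCut FDR annotation cutoff (default 0.25).
#' @param consensusReps consensus clustering repetitions (default 5000).
#' @param maxK consensus scan upper bound (default 7).
#' @param alpha,minGenes ssGSEA parameters, see [ssgseaMatrix()].
#' @param normalizationOrder,background,pseudocount normalization
#'   parameters, see [normalizePipeline()].
#' @param varianceMode unpaired t-test variance mode (default
#'   `"pooled"`).
#' @param seed RNG seed for consensus clustering.
#' @return a report list with elements `expr`, `normalizationReport`,
#'   `enrichment` (raw + `z`), `icr` (scores, consensus, classes),
#'   `differential` (per design: full table, `degs`,
#'   `categoryEnrichment`), `scoreFoldChanges` (per design),
#'   `signatureChange` (paired design), `pca`, `metadata`.
#' @export
runFullAnalysis <- function(counts = NULL, expr = NULL, annotation = NULL,
                            signatures, categories = NULL,
                            comparisons = STUDY_DESIGNS, pCut = 0.05,
                            fdrCut = 0.25, consensusReps = 5000, maxK = 7,
                            alpha = 0.25, minGenes = 3,
                            normalizationOrder = "housekeeping_first",
                            background = "mean", pseudocount = 1,
                            varianceMode = "pooled", seed = 1) {
  if (is.null(counts) && is.null(expr))
    stop("provide 'counts' or a pre-normalized 'expr'")
  normReport <- NULL
  if (is.null(expr)) {
    if (is.null(categories)) categories <- geneCategories(counts)
    norm <- normalizePipeline(counts, order = normalizationOrder,
                              background = background,
                              pseudocount = pseudocount)
    expr <- norm$expr
    normReport <- norm$report
  }
  if (is.null(annotation)) {
    annotation <- sampleAnnotation(expr)
    if (!"sample_id" %in% colnames(annotation))
      stop("no sample annotation available; pass 'annotation'")
    annotation <- validateSampleAnnotation(annotation)
  }
  m <- exprMatrix(expr)

  ## ssGSEA on leukocyte signatures + the pooled ICR set
  if (is(signatures, "GeneSetCollection")) signatures <- geneSets(signatures)
  if (!"ICR" %in% names(signatures))
    signatures <- c(signatures, list(ICR = icrSignatureGenes()))
  es <- ssgseaMatrix(m, signatures, alpha = alpha, minGenes = minGenes)
  esZ <- zscoreRows(es)

  ## ICR scoring and consensus classification
  scores <- icrScore(m)
  icrPresent <- intersect(icrSignatureGenes(), rownames(m))
  icrFeatures <- t(m[icrPresent, , drop = FALSE])
  consensus <- consensusCluster(icrFeatures, maxK = maxK,
                                reps = consensusReps, seed = seed)
  classes <- assignIcrClasses(consensus, scores, k = 3)

  ## differential expression + enrichment per comparison
  background_genes <- rownames(m)
  differential <- list()
  for (design in comparisons) {
    differential[[design]] <- tryCatch({
      res <- runComparison(m, annotation, design = design,
                           varianceMode = varianceMode,
                           categories = categories)
      degs <- selectDegs(res, pCut = pCut, fdrCut = fdrCut)
      enr <- if (!is.null(categories) && nrow(degs) > 0)
        categoryEnrichment(degs$gene, categories, background_genes)
      list(table = res, degs = degs, categoryEnrichment = enr)
    }, error = function(e) paste("comparison failed:", conditionMessage(e)))
  }

  ## enrichment-score fold changes per comparison
  sfc <- list()
  for (design in comparisons) {
    sfc[[design]] <- tryCatch(
      scoreFoldChange(es, annotation, design = design,
                      varianceMode = varianceMode),
      error = function(e) paste("comparison failed:", conditionMessage(e)))
  }

  ## net fold-change percentages for the paired design
  sigChange <- tryCatch({
    pairs <- completePairs(annotation)
    signatureChange(m, pairs$post, pairs$pre, signatures)
  }, error = function(e) paste("comparison failed:", conditionMessage(e)))

  pca <- runPCA(m)

  list(expr = expr, normalizationReport = normReport,
       enrichment = list(raw = es, z = esZ),
       icr = list(scores = scores, consensus = consensus,
                  classes = classes),
       differential = differential, scoreFoldChanges = sfc,
       signatureChange = sigChange, pca = pca,
       metadata = list(
         package = as.character(utils::packageVersion("ICRpanel")),
         seed = seed, comparisons = comparisons,
         parameters = list(pCut = pCut, fdrCut = fdrCut,
                           consensusReps = consensusReps, maxK = maxK,
                           alpha = alpha, minGenes = minGenes,
                           normalizationOrder = normalizationOrder,
                           background = background,
                           pseudocount = pseudocount,
                           varianceMode = varianceMode),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Write the tabular parts of a report bundle
#'
#' Emits normalized expression, enrichment matrices, ICR scores/classes,
#' DEG tables, category enrichment, score fold changes and PCA
#' coordinates as TSV files.
#'
#' @param report output of [runFullAnalysis()].
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
writeReportBundle <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[[name]] <<- p
  }
  writeExpressionTable(exprMatrix(report$expr),
                       file.path(dir, "normalized_log2.tsv"))
  paths[["normalized_log2.tsv"]] <- file.path(dir, "normalized_log2.tsv")
  writeExpressionTable(report$enrichment$raw,
                       file.path(dir, "ssgsea_scores.tsv"),
                       idColumn = "signature")
  writeExpressionTable(report$enrichment$z,
                       file.path(dir, "ssgsea_zscores.tsv"),
                       idColumn = "signature")
  icrTab <- data.frame(sample_id = names(report$icr$scores),
                       icr_score = unname(report$icr$scores),
                       icr_class = as.character(
                         report$icr$classes[names(report$icr$scores)]),
                       stringsAsFactors = FALSE)
  wr(icrTab, "icr_classes.tsv")
  for (design in names(report$differential)) {
    d <- report$differential[[design]]
    if (is.list(d)) {
      wr(d$table, paste0("deg_", design, ".tsv"))
      if (!is.null(d$categoryEnrichment))
        wr(d$categoryEnrichment, paste0("enrichment_", design, ".tsv"))
    }
  }
  for (design in names(report$scoreFoldChanges)) {
    d <- report$scoreFoldChanges[[design]]
    if (is.data.frame(d)) wr(d, paste0("score_fc_", design, ".tsv"))
  }
  if (is.data.frame(report$signatureChange))
    wr(report$signatureChange, "signature_change.tsv")
  pcaTab <- data.frame(sample_id = rownames(report$pca$coordinates),
                       report$pca$coordinates, stringsAsFactors = FALSE)
  wr(pcaTab, "pca_coordinates.tsv")
  invisible(unlist(paths))
}
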