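## Synthetic paired-design panel datasets with recoverable ground truth.
## The generator emulates an nCounter-style immune panel profiled on paired
## pre/post tumor biopsies: lognormal per-gene baselines, negative-binomial
## count noise, lognormal library-size factors, housekeeping and
## negative/positive control probes, and two injected immune effects (an
## ICR up-shift in responder post-treatment samples and a baseline
## antigen-presentation up-shift in complete responders).

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.SIGNATURE_NAMES <- c(
  "T_cells", "Cytotoxic_cells", "NK_cells", "NK_CD56bright_cells",
  "Macrophages", "B_cells", "aDC", "iDC", "Neutrophils", "Mast_cells",
  "Tcm_cells", "Th1_cells")

.CATEGORY_NAMES <- c(
  "Adaptive immune response", "Innate immune response",
  "Chemokines and receptors", "Antigen processing and presentation",
  "Cytotoxicity", "T-cell activation", "NK cell functions",
  "Regulation of immune response")

#' Generate a synthetic paired panel dataset
#'
#' Draws a complete paired-design count dataset under a
#' [SyntheticConfig-class]: `2 * nPatients` samples (one `pre` and one
#' `post` biopsy per patient), negative-binomial counts with mean
#' `baseline * libraryFactor * 2^effect`, housekeeping probes with stable
#' high baselines, negative-control probes an order of magnitude below the
#' endogenous median, and positive-control probes on a fixed ladder. The
#' 20 ICR genes head the endogenous panel under their real symbols so ICR
#' scoring works out of the box. Identical seeds give bitwise-identical
#' output; the caller's RNG state is left untouched.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with elements `counts` (a [PanelCountSet-class] carrying
#'   the annotation in `colData`), `annotation` (`data.frame`), `truth`
#'   (list: `icrGenes`, `antigenGenes`, `trueEffects` genes x samples log2
#'   effect matrix, `libraryFactors`, `baselines`, `signatures`,
#'   `perturbedSignatures`, `categories`).
#' @export
generateDataset <- function(config = SyntheticConfig()) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  .withSeed(config@seed, {
    icrGenes <- icrSignatureGenes()
    nOther <- config@nEndogenous - length(icrGenes)
    endo <- c(icrGenes, sprintf("SYNG%04d", seq_len(nOther)))
    hk <- sprintf("HK%02d", seq_len(config@nHousekeeping))
    neg <- sprintf("NEG%02d", seq_len(config@nNegativeControls))
    pos <- if (config@nPositiveControls > 0)
      sprintf("POS%02d", seq_len(config@nPositiveControls)) else character(0)
    genes <- c(endo, hk, neg, pos)
    probeClass <- c(rep("endogenous", length(endo)),
                    rep("housekeeping", length(hk)),
                    rep("negative_control", length(neg)),
                    rep("positive_control", length(pos)))

    ## samples and clinical design
    patients <- sprintf("P%d", seq_len(config@nPatients))
    response <- rep("NR", config@nPatients)
    if (config@nCR > 0) response[seq_len(config@nCR)] <- "CR"
    if (config@nPR > 0)
      response[config@nCR + seq_len(config@nPR)] <- "PR"
    nrIdx <- which(response == "NR")
    hr <- rep("Pos", config@nPatients)
    nHrNeg <- min(length(nrIdx), ceiling(config@nPatients / 8))
    if (nHrNeg > 0) hr[utils::tail(nrIdx, nHrNeg)] <- "Neg"
    her2 <- ifelse(seq_len(config@nPatients) %% 2 == 1, "Pos", "Neg")
    annotation <- data.frame(
      sample_id = as.vector(t(outer(patients, c("pre", "post"),
                                    paste, sep = "_"))),
      patient_id = rep(patients, each = 2),
      timepoint = rep(c("pre", "post"), config@nPatients),
      response = rep(response, each = 2),
      hr_status = rep(hr, each = 2),
      her2_status = rep(her2, each = 2),
      stringsAsFactors = FALSE)
    annotation <- validateSampleAnnotation(annotation)
    samples <- annotation$sample_id

    ## per-gene baselines (counts scale)
    muEndo <- stats::rlnorm(length(endo), config@baselineLogMean,
                            config@baselineLogSd)
    muHk <- stats::rlnorm(length(hk), config@baselineLogMean + 1.5, 0.3)
    muNeg <- rep(stats::median(muEndo) / 10, length(neg))
    posLadder <- c(8192, 2048, 512, 128, 32, 8)
    muPos <- rep_len(posLadder, length(pos))
    baselines <- stats::setNames(c(muEndo, muHk, muNeg, muPos), genes)

    ## library-size factors (lognormal, mean 1)
    sdlog <- sqrt(log(1 + config@librarySizeCv^2))
    libFactors <- stats::setNames(
      stats::rlnorm(length(samples), -sdlog^2 / 2, sdlog), samples)

    ## injected log2 effects
    antigenGenes <- sample(setdiff(endo, icrGenes), 15)
    effects <- matrix(0, nrow = length(genes), ncol = length(samples),
                      dimnames = list(genes, samples))
    responderPost <- annotation$sample_id[
      annotation$response %in% c("CR", "PR") & annotation$timepoint == "post"]
    crSamples <- annotation$sample_id[annotation$response == "CR"]
    effects[icrGenes, responderPost] <-
      effects[icrGenes, responderPost] + config@icrPostEffectLog2
    effects[antigenGenes, crSamples] <-
      effects[antigenGenes, crSamples] + config@baselineResponderEffectLog2

    mu <- baselines * t(t(2^effects) * libFactors)
    countsVec <- stats::rnbinom(length(mu), mu = as.vector(mu),
                                size = config@nbDispersion)
    counts <- matrix(as.numeric(countsVec), nrow = length(genes),
                     dimnames = dimnames(mu))

    ## disjoint leukocyte signatures (5-30 genes) from the endogenous panel
    pool <- sample(endo)
    maxSize <- min(30L, max(3L, floor(length(pool) / length(.SIGNATURE_NAMES))))
    minSize <- min(5L, maxSize)
    sizes <- if (minSize == maxSize)
      rep(minSize, length(.SIGNATURE_NAMES))
    else sample(minSize:maxSize, length(.SIGNATURE_NAMES), replace = TRUE)
    signatures <- list()
    offset <- 0
    for (i in seq_along(.SIGNATURE_NAMES)) {
      if (length(pool) - offset < sizes[i]) break
      signatures[[.SIGNATURE_NAMES[i]]] <- pool[offset + seq_len(sizes[i])]
      offset <- offset + sizes[i]
    }
    affected <- c(icrGenes, antigenGenes)
    perturbed <- names(signatures)[
      vapply(signatures, function(s) any(s %in% affected), TRUE)]

    ## overlapping annotation categories; antigen category contains the
    ## injected antigen-presentation genes
    categories <- lapply(.CATEGORY_NAMES, function(cat)
      sample(endo, min(length(endo), sample(20:60, 1))))
    names(categories) <- .CATEGORY_NAMES
    categories[["Antigen processing and presentation"]] <-
      unique(c(antigenGenes,
               categories[["Antigen processing and presentation"]]))

    pcs <- PanelCountSet(counts, probeClass = probeClass,
                         categories = categories, sampleData = annotation)
    truth <- list(icrGenes = icrGenes, antigenGenes = antigenGenes,
                  trueEffects = effects, libraryFactors = libFactors,
                  baselines = baselines, signatures = signatures,
                  perturbedSignatures = perturbed, categories = categories)
    list(counts = pcs, annotation = annotation, truth = truth)
  })
}

#' Write a synthetic dataset as a plain-text fixture bundle
#'
#' Emits `counts.tsv`, `panel.tsv`, `annotation.tsv`, `icr_genes.gmt`
#' (the four ICR functional categories), `signatures.gmt` (leukocyte
#' signatures plus the pooled ICR set) and `categories.gmt`, all readable
#' by the package's readers.
#'
#' @param dataset output of [generateDataset()].
#' @param dir output directory (created if missing).
#' @return named character vector of file paths, invisibly.
#' @export
writeFixtureBundle <- function(dataset, dir) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create directory: ", dir)
  pcs <- dataset$counts
  paths <- c(counts = file.path(dir, "counts.tsv"),
             panel = file.path(dir, "panel.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             icr = file.path(dir, "icr_genes.gmt"),
             signatures = file.path(dir, "signatures.gmt"),
             categories = file.path(dir, "categories.gmt"))
  writeExpressionTable(counts(pcs), paths[["counts"]])
  catList <- as.list(rowData(pcs)$categories)
  panel <- data.frame(
    gene_id = rownames(pcs),
    probe_class = probeClass(pcs),
    categories = vapply(catList, paste, "", collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(panel, paths[["panel"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeSampleAnnotation(dataset$annotation, paths[["annotation"]])
  writeGMT(icrGeneSets(), paths[["icr"]])
  sigs <- dataset$truth$signatures
  sigs[["ICR"]] <- dataset$truth$icrGenes
  writeGMT(sigs, paths[["signatures"]])
  writeGMT(dataset$truth$categories, paths[["categories"]])
  invisible(paths)
}

#' Read back a fixture bundle
#'
#' @param dir directory written by [writeFixtureBundle()].
#' @return list with `counts` ([PanelCountSet-class]), `annotation`,
#'   `icr`, `signatures`, `categories` (the last three
#'   [GeneSetCollection-class]s).
#' @export
readFixtureBundle <- function(dir) {
  list(counts = readPanelCounts(file.path(dir, "counts.tsv"),
                                file.path(dir, "panel.tsv"),
                                file.path(dir, "annotation.tsv")),
       annotation = readSampleAnnotation(file.path(dir, "annotation.tsv")),
       icr = readGMT(file.path(dir, "icr_genes.gmt")),
       signatures = readGMT(file.path(dir, "signatures.gmt")),
       categories = readGMT(file.path(dir, "categories.gmt")))
}

#' Simulate samples with planted ICR expression levels
#'
#' Builds a small log2 expression matrix over the 20 ICR genes in which
#' groups of samples carry additive log2 shifts (default 0/1/2) over shared
#' per-gene baselines, with Gaussian noise. Used to test recovery of the
#' ICR High/Medium/Low structure by consensus clustering.
#'
#' @param nPerGroup samples per planted level.
#' @param shifts numeric vector of log2 shifts, one per level.
#' @param noiseSd per-gene, per-sample Gaussian noise sd (log2 units).
#' @param seed RNG seed.
#' @return list with `expr` (20 x n matrix) and `labels` (integer planted
#'   level per sample).
#' @export
simulateIcrLevels <- function(nPerGroup = 6, shifts = c(0, 1, 2),
                              noiseSd = 0.5, seed = 1) {
  .withSeed(seed, {
    genes <- icrSignatureGenes()
    base <- stats::rnorm(length(genes), mean = 8, sd = 1)
    labels <- rep(seq_along(shifts), each = nPerGroup)
    n <- length(labels)
    expr <- matrix(base, nrow = length(genes), ncol = n) +
      matrix(rep(shifts[labels], each = length(genes)), nrow = length(genes)) +
      matrix(stats::rnorm(length(genes) * n, sd = noiseSd),
             nrow = length(genes))
    dimnames(expr) <- list(genes, sprintf("S%02d", seq_len(n)))
    list(expr = expr, labels = labels)
  })
}
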