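## Readers/writers for the artifact's standard text formats: expression
## tables (TSV/CSV), GMT gene sets, sample annotation tables, result tables.
## Delimiter is decided by extension (.tsv -> tab, .csv -> comma); no
## sniffing. Gene symbols are matched case-sensitively throughout.

.delimFor <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, tsv = "\t", txt = "\t", csv = ",",
         stop("unsupported extension '.", ext, "' (use .tsv or .csv): ", path))
}

#' Read a delimited expression table
#'
#' Reads a genes x samples (or samples x genes) numeric table with one
#' header row of ids and the row ids in the first column. Parsing is
#' strict: duplicate ids and non-numeric or missing cells are errors (the
#' panel yields complete matrices), and the file's row/column order is
#' preserved.
#'
#' @param path path to a `.tsv` or `.csv` file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return numeric matrix, genes x samples.
#' @export
readExpressionTable <- function(path,
                                orientation = c("genes_in_rows",
                                                "samples_in_rows")) {
  orientation <- match.arg(orientation)
  delim <- .delimFor(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("expression table needs an id column plus data: ",
                         path)
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  colIds <- colnames(df)[-1]
  if (anyDuplicated(colIds))
    stop("duplicate column ids in ", path, ": ",
         paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    stop(sprintf(
      "non-numeric or missing cell at row '%s', column '%s' in %s (value: '%s')",
      ids[b[1]], colIds[b[2]], path, raw[b[1], b[2]]))
  }
  dimnames(num) <- list(ids, colIds)
  if (orientation == "samples_in_rows") num <- t(num)
  num
}

#' Write an expression table
#'
#' @param mat numeric matrix with dimnames.
#' @param path output `.tsv`/`.csv` path; delimiter follows the extension.
#' @param idColumn header of the first (id) column.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(mat, path, idColumn = "gene_id") {
  delim <- .delimFor(path)
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(mat))
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard Broad dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`. Lines with fewer than three fields
#' and duplicate set names are rejected; member order is preserved.
#'
#' @param path path to a GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields in ", path)
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms))
    stop("duplicate gene set name in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  GeneSetCollection(sets)
}

#' Write gene sets in GMT format
#'
#' @param sets a [GeneSetCollection-class] or named list.
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is(sets, "GeneSetCollection")) sets <- geneSets(sets)
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.TIMEPOINTS <- c("pre", "post")
.RESPONSES <- c("CR", "PR", "NR")
.POSNEG <- c("Pos", "Neg")

#' Read a sample annotation table
#'
#' Expects columns `sample_id`, `patient_id`, `timepoint` (`pre`/`post`),
#' `response` (`CR`/`PR`/`NR`), `hr_status` and `her2_status` (`Pos`/`Neg`).
#' Enum tokens are validated; each patient may have at most one `pre` and
#' one `post` sample, and its response label must be constant.
#'
#' @param path path to a `.tsv`/`.csv` annotation table.
#' @return `data.frame` of validated annotations (one row per sample).
#' @export
readSampleAnnotation <- function(path) {
  delim <- .delimFor(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  validateSampleAnnotation(df)
}

#' Validate a sample annotation data frame
#'
#' @param df annotation `data.frame` (see [readSampleAnnotation()]).
#' @return the validated `data.frame` (character columns, row names =
#'   sample ids).
#' @export
validateSampleAnnotation <- function(df) {
  need <- c("sample_id", "patient_id", "timepoint", "response",
            "hr_status", "her2_status")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation is missing required columns: ",
         paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in need) df[[col]] <- as.character(df[[col]])
  checkEnum <- function(col, allowed) {
    bad <- setdiff(unique(df[[col]]), allowed)
    if (length(bad))
      stop("unknown ", col, " token(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")")
  }
  checkEnum("timepoint", .TIMEPOINTS)
  checkEnum("response", .RESPONSES)
  checkEnum("hr_status", .POSNEG)
  checkEnum("her2_status", .POSNEG)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  dup <- duplicated(df[, c("patient_id", "timepoint")])
  if (any(dup))
    stop("patient(s) with two samples at the same timepoint: ",
         paste(unique(df$patient_id[dup]), collapse = ", "))
  respPerPatient <- tapply(df$response, df$patient_id,
                           function(x) length(unique(x)))
  if (any(respPerPatient > 1))
    stop("response label not constant within patient(s): ",
         paste(names(respPerPatient)[respPerPatient > 1], collapse = ", "))
  rownames(df) <- df$sample_id
  df
}

#' Write a sample annotation table
#'
#' @param annotation annotation `data.frame`.
#' @param path output `.tsv`/`.csv` path.
#' @return `path`, invisibly.
#' @export
writeSampleAnnotation <- function(annotation, path) {
  delim <- .delimFor(path)
  utils::write.table(annotation, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Complete pre/post pairs in an annotation
#'
#' @param annotation validated annotation `data.frame`.
#' @return `data.frame` with columns `patient_id`, `pre`, `post`,
#'   `response`; one row per patient having both timepoints.
#' @export
completePairs <- function(annotation) {
  pats <- unique(annotation$patient_id)
  rows <- lapply(pats, function(p) {
    sub <- annotation[annotation$patient_id == p, , drop = FALSE]
    pre <- sub$sample_id[sub$timepoint == "pre"]
    post <- sub$sample_id[sub$timepoint == "post"]
    if (length(pre) == 1 && length(post) == 1)
      data.frame(patient_id = p, pre = pre, post = post,
                 response = sub$response[1], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(patient_id = character(), pre = character(),
                      post = character(), response = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Summarize a sample annotation at the patient level
#'
#' Computes patient counts, complete pre/post pair counts, response-group
#' sizes, and the percentage of hormone-receptor-positive and HER2-positive
#' patients (each patient counted once).
#'
#' @param annotation validated annotation `data.frame`.
#' @return list with `nPatients`, `nSamples`, `nCompletePairs`,
#'   `responseCounts`, `hrPositivePercent`, `her2PositivePercent`.
#' @export
annotationSummary <- function(annotation) {
  perPatient <- annotation[!duplicated(annotation$patient_id), , drop = FALSE]
  list(
    nPatients = nrow(perPatient),
    nSamples = nrow(annotation),
    nCompletePairs = nrow(completePairs(annotation)),
    responseCounts = table(perPatient$response),
    hrPositivePercent = 100 * mean(perPatient$hr_status == "Pos"),
    her2PositivePercent = 100 * mean(perPatient$her2_status == "Pos"))
}

#' Read a panel description table
#'
#' Two-to-three-column table `gene_id`, `probe_class`, optional
#' comma-separated `categories`.
#'
#' @param path `.tsv`/`.csv` path.
#' @return `data.frame` with `gene_id`, `probe_class`, `categories` (list
#'   column).
#' @export
readPanelInfo <- function(path) {
  delim <- .delimFor(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (!all(c("gene_id", "probe_class") %in% colnames(df)))
    stop("panel table needs columns gene_id and probe_class: ", path)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in panel table: ", path)
  bad <- setdiff(unique(df$probe_class), PROBE_CLASSES)
  if (length(bad))
    stop("unknown probe_class token(s): ", paste(bad, collapse = ", "))
  df$categories <- if ("categories" %in% colnames(df))
    strsplit(ifelse(is.na(df$categories), "", df$categories), ";",
             fixed = TRUE)
  else rep(list(character(0)), nrow(df))
  df
}

#' Assemble a PanelCountSet from count, panel and annotation files
#'
#' @param countsPath counts table (genes x samples).
#' @param panelPath panel description table (see [readPanelInfo()]).
#' @param annotationPath optional sample annotation table.
#' @return A [PanelCountSet-class].
#' @export
readPanelCounts <- function(countsPath, panelPath, annotationPath = NULL) {
  counts <- readExpressionTable(countsPath)
  panel <- readPanelInfo(panelPath)
  if (!setequal(rownames(counts), panel$gene_id))
    stop("counts and panel tables list different genes")
  panel <- panel[match(rownames(counts), panel$gene_id), ]
  categories <- .invertCategories(panel)
  ann <- if (!is.null(annotationPath)) readSampleAnnotation(annotationPath)
  PanelCountSet(counts, probeClass = panel$probe_class,
                categories = categories, sampleData = ann)
}

.invertCategories <- function(panel) {
  cats <- unique(unlist(panel$categories))
  cats <- cats[nzchar(cats)]
  if (length(cats) == 0) return(NULL)
  out <- lapply(cats, function(cat)
    panel$gene_id[vapply(panel$categories, function(x) cat %in% x, TRUE)])
  names(out) <- cats
  out
}

#' Write a differential expression result table
#'
#' Emits the `Gene, p value, q value, FC, Annotation` layout used for
#' DEG reporting.
#'
#' @param result `data.frame` from [runComparison()] or [selectDegs()].
#' @param path output `.tsv`/`.csv` path.
#' @return `path`, invisibly.
#' @export
writeResultTable <- function(result, path) {
  delim <- .delimFor(path)
  utils::write.table(result, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
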