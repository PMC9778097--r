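#' Read a count matrix from disk
#'
#' Two plain-text formats are supported.  `"tsv"`: tab-separated, UTF-8,
#' header row whose first cell is literally `feature_id` followed by the
#' sample identifiers; one row per feature, identifiers unquoted.  `"mtx"`:
#' matrix-market coordinate format with companion identifier lists
#' `<stem>.features.txt` and `<stem>.samples.txt` (one id per line).
#' Non-integer or negative entries, duplicate identifiers, ragged rows and
#' malformed headers are rejected with errors naming the offending line.
#'
#' @param path file to read (for `"mtx"`, the `.mtx` file).
#' @param format `"tsv"` (default) or `"mtx"`.
#' @param annotation optional path of a sample-annotation TSV (see
#'   [readSampleAnnotation()]) whose class labels are attached to the result.
#' @return a [CountDataSet-class].
#' @seealso [writeCounts()]
#' @export
readCounts <- function(path, format = c("tsv", "mtx"), annotation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("count file not found: ", path)
  cds <- switch(format, tsv = readCountsTSV(path), mtx = readCountsMTX(path))
  if (!is.null(annotation)) {
    ann <- readSampleAnnotation(annotation)
    cds <- attachAnnotation(cds, ann)
  }
  cds
}

readCountsTSV <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("file ", path, " has no data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (length(header) < 2L || header[1L] != "feature_id")
    stop("malformed header at line 1: first cell must be 'feature_id' ",
         "followed by sample identifiers")
  sampleIds <- header[-1L]
  if (anyDuplicated(sampleIds))
    stop("duplicate sample identifiers in header (line 1): ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  width <- length(header)
  body <- cells[-1L]
  lens <- lengths(body)
  if (any(lens != width)) {
    bad <- which(lens != width)[1L]
    stop(sprintf("ragged row at line %d: %d fields, expected %d",
                 bad + 1L, lens[bad], width))
  }
  featureIds <- vapply(body, `[[`, character(1L), 1L)
  if (anyDuplicated(featureIds))
    stop("duplicate feature identifiers (first at line ",
         which(duplicated(featureIds))[1L] + 1L, "): ",
         featureIds[duplicated(featureIds)][1L])
  vals <- suppressWarnings(
    vapply(body, function(r) as.numeric(r[-1L]), numeric(width - 1L)))
  vals <- if (width == 2L) matrix(vals, nrow = 1L) else t(vals)
  bad <- which(is.na(vals) | vals < 0 | !isWholeNumber(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    r <- bad[1L, 1L]; c <- bad[1L, 2L]
    stop(sprintf(
      "invalid count at line %d, column %d (feature '%s', sample '%s'): entries must be non-negative integers",
      r + 1L, c + 1L, featureIds[r], sampleIds[c]))
  }
  storage.mode(vals) <- "integer"
  dimnames(vals) <- list(featureIds, sampleIds)
  CountDataSet(vals)
}

readCountsMTX <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  stem <- sub("\\.mtx$", "", path)
  fFile <- paste0(stem, ".features.txt")
  sFile <- paste0(stem, ".samples.txt")
  if (!file.exists(fFile) || !file.exists(sFile))
    stop("companion identifier lists not found: ", fFile, " / ", sFile)
  featureIds <- readLines(fFile); sampleIds <- readLines(sFile)
  if (length(featureIds) != nrow(m))
    stop("feature id list length (", length(featureIds),
         ") does not match matrix rows (", nrow(m), ")")
  if (length(sampleIds) != ncol(m))
    stop("sample id list length (", length(sampleIds),
         ") does not match matrix columns (", ncol(m), ")")
  if (any(m < 0) || !all(isWholeNumber(m)))
    stop("matrix-market entries must be non-negative integers")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(featureIds, sampleIds)
  CountDataSet(m)
}

#' Write a count matrix to disk
#'
#' Inverse of [readCounts()]; `read(write(x)) == x` for both formats.
#'
#' @param object a [CountDataSet-class] (or count matrix).
#' @param path output file; for `"mtx"` the companion identifier lists are
#'   written next to it.
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
writeCounts <- function(object, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  cnt <- if (is(object, "CountDataSet")) counts(object) else as.matrix(object)
  if (format == "tsv") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste(c("feature_id", colnames(cnt)), collapse = "\t"), con)
    body <- paste(rownames(cnt),
                  apply(cnt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  } else {
    Matrix::writeMM(Matrix::Matrix(cnt, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(cnt), paste0(stem, ".features.txt"))
    writeLines(colnames(cnt), paste0(stem, ".samples.txt"))
  }
  invisible(path)
}

#' Read and write sample annotations
#'
#' The annotation TSV has a header `sample_id<TAB>class[<TAB>subgroup]`;
#' `class` must be 1 or 2.  `attachAnnotation()` matches annotation rows to
#' the dataset's sample identifiers (every column must be annotated exactly
#' once).
#'
#' @param path annotation TSV path.
#' @return `readSampleAnnotation`: a data.frame with columns `sample_id`,
#'   `class` and optionally `subgroup`.
#' @export
readSampleAnnotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(ann)))
    stop("annotation must have columns 'sample_id' and 'class': ", path)
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation: ",
         ann$sample_id[duplicated(ann$sample_id)][1L])
  if (!all(ann$class %in% c(1L, 2L)))
    stop("annotation classes must be 1 or 2")
  ann
}

#' @rdname readSampleAnnotation
#' @param object a [CountDataSet-class].
#' @param ann annotation data.frame from `readSampleAnnotation`.
#' @return `attachAnnotation`: the dataset with `colData$class` (and
#'   `subgroup` if present) filled in.
#' @export
attachAnnotation <- function(object, ann) {
  idx <- match(colnames(object), ann$sample_id)
  if (anyNA(idx))
    stop("samples without annotation: ",
         paste(head(colnames(object)[is.na(idx)], 5L), collapse = ", "))
  SummarizedExperiment::colData(object)$class <- as.integer(ann$class[idx])
  if ("subgroup" %in% names(ann))
    SummarizedExperiment::colData(object)$subgroup <-
      as.integer(ann$subgroup[idx])
  validObject(object)
  object
}

#' @rdname readSampleAnnotation
#' @export
writeSampleAnnotation <- function(object, path) {
  cls <- classLabels(object)
  if (is.null(cls)) stop("dataset carries no class labels")
  df <- data.frame(sample_id = colnames(object), class = cls)
  sg <- SummarizedExperiment::colData(object)$subgroup
  if (!is.null(sg)) df$subgroup <- sg
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read simulation ground truth
#'
#' TSV with columns `feature_id`, `de_flag` (0/1), `true_lfc` (log2),
#' `block_id` (`NA` for unblocked features).
#'
#' @param object a simulated [CountDataSet-class].
#' @param path TSV path.
#' @export
writeGroundTruth <- function(object, path) {
  if (is.null(deFlags(object))) stop("dataset carries no ground truth")
  df <- data.frame(feature_id = rownames(object),
                   de_flag = as.integer(deFlags(object)),
                   true_lfc = trueLfc(object),
                   block_id = blockIds(object))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @return `readGroundTruth`: a [S4Vectors::DataFrame] with logical
#'   `de_flag`, numeric `true_lfc`, integer `block_id`, feature ids as row
#'   names.
#' @export
readGroundTruth <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  S4Vectors::DataFrame(de_flag = as.logical(df$de_flag),
                       true_lfc = df$true_lfc,
                       block_id = as.integer(df$block_id),
                       row.names = df$feature_id)
}
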