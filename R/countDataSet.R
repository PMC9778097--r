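#' Build a CountDataSet from a count matrix
#'
#' @param counts non-negative integer-valued matrix, features in rows and
#'   samples in columns. Dimnames are required; defaults `gene_i` /
#'   `sample_j` are filled in when absent.
#' @param classLabels optional vector of 1/2 class labels, one per sample.
#' @param subgroup optional integer subgroup per sample (class-1 subgroup
#'   structure; `NA` elsewhere).
#' @param rowData optional [S4Vectors::DataFrame] of per-feature metadata
#'   (e.g. simulation ground truth).
#' @param metadata optional list stored in `metadata()`.
#' @return a [CountDataSet-class].
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4)
#' cds <- CountDataSet(m, classLabels = c(1, 1, 2, 2))
#' classLabels(cds)
#' @export
CountDataSet <- function(counts, classLabels = NULL, subgroup = NULL,
                         rowData = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  if (!is.null(classLabels)) {
    if (length(classLabels) != ncol(counts))
      stop("classLabels must have one entry per sample (", ncol(counts),
           "), got ", length(classLabels))
    cd$class <- as.integer(classLabels)
  }
  if (!is.null(subgroup)) cd$subgroup <- as.integer(subgroup)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, metadata = metadata)
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  new("CountDataSet", se)
}

#' Accessors for CountDataSet content
#'
#' `counts()` returns the integer count matrix, `classLabels()` the 1/2
#' class labels, and `deFlags()`, `trueLfc()`, `blockIds()` the simulation
#' ground truth carried in `rowData` (available for simulated datasets).
#'
#' @param object a [CountDataSet-class].
#' @return `counts`: matrix; `classLabels`: integer vector (or `NULL`);
#'   `deFlags`: logical vector; `trueLfc`: numeric vector (log2);
#'   `blockIds`: integer vector with `NA` for unblocked features.
#' @name countdataset-accessors
#' @aliases counts classLabels deFlags trueLfc blockIds
NULL

#' @rdname countdataset-accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname countdataset-accessors
#' @export
setMethod("counts", "CountDataSet", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname countdataset-accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname countdataset-accessors
#' @export
setMethod("classLabels", "CountDataSet", function(object) {
  SummarizedExperiment::colData(object)$class
})

#' @rdname countdataset-accessors
#' @export
setGeneric("deFlags", function(object) standardGeneric("deFlags"))
#' @rdname countdataset-accessors
#' @export
setMethod("deFlags", "CountDataSet", function(object) {
  SummarizedExperiment::rowData(object)$de_flag
})

#' @rdname countdataset-accessors
#' @export
setGeneric("trueLfc", function(object) standardGeneric("trueLfc"))
#' @rdname countdataset-accessors
#' @export
setMethod("trueLfc", "CountDataSet", function(object) {
  SummarizedExperiment::rowData(object)$true_lfc
})

#' @rdname countdataset-accessors
#' @export
setGeneric("blockIds", function(object) standardGeneric("blockIds"))
#' @rdname countdataset-accessors
#' @export
setMethod("blockIds", "CountDataSet", function(object) {
  SummarizedExperiment::rowData(object)$block_id
})

setMethod("show", "CountDataSet", function(object) {
  cat("CountDataSet: ", nrow(object), " features x ", ncol(object),
      " samples\n", sep = "")
  cls <- classLabels(object)
  if (!is.null(cls))
    cat("  classes: ", sum(cls == 1L), " / ", sum(cls == 2L), "\n", sep = "")
  fl <- deFlags(object)
  if (!is.null(fl))
    cat("  ground truth: ", sum(fl), " DE features, ",
        sum(!is.na(blockIds(object))), " in correlation blocks\n", sep = "")
  cat("  overall mean count: ",
      format(mean(counts(object)), digits = 4), "\n", sep = "")
})

# Class labels required by two-class operations; fails with a clear message
# when the annotation is absent or degenerate.
requireTwoClasses <- function(object, minPerClass = 1L) {
  cls <- classLabels(object)
  if (is.null(cls)) stop("sample class labels are required (colData$class)")
  n1 <- sum(cls == 1L); n2 <- sum(cls == 2L)
  if (n1 < minPerClass || n2 < minPerClass)
    stop(sprintf("need >= %d samples per class, have %d / %d",
                 minPerClass, n1, n2))
  cls
}
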