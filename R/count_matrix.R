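#' Construct a sample sheet
#'
#' A sample sheet maps each sample to a tissue label and a biological
#' replicate identifier. It defines the tissue grouping used by the
#' differential-expression, PUR and tau stages.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param tissue Character vector of tissue labels, one per sample.
#' @param replicate Character vector of replicate (genotype) identifiers.
#' @return A `data.frame` of class `sample_sheet` with columns
#'   `sample_id`, `tissue`, `replicate`.
#' @examples
#' sample_sheet(c("n1", "n2", "p1", "p2"),
#'              c("needle", "needle", "phloem", "phloem"),
#'              c("r1", "r2", "r1", "r2"))
#' @export
sample_sheet <- function(sample_id, tissue, replicate) {
  sample_id <- as.character(sample_id)
  tissue <- as.character(tissue)
  replicate <- as.character(replicate)
  if (length(sample_id) != length(tissue) ||
      length(sample_id) != length(replicate)) {
    stop("sample_id, tissue and replicate must have equal length",
         call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(tissue, replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (tissue, replicate) pair in sample sheet", call. = FALSE)
  }
  out <- data.frame(sample_id = sample_id, tissue = tissue,
                    replicate = replicate, stringsAsFactors = FALSE)
  class(out) <- c("sample_sheet", "data.frame")
  out
}

#' Construct an expression matrix with a declared value kind
#'
#' The central container of the pipeline: a genes x samples numeric matrix
#' tagged with the kind of values it holds (`raw` counts, `tpm`, `tmm`
#' normalized values or `log2tmm`) and the sample sheet describing its
#' columns.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids). All values must be
#'   non-negative.
#' @param kind One of `"raw"`, `"tpm"`, `"tmm"`, `"log2tmm"`.
#' @param sheet A [sample_sheet()] covering every column.
#' @return An object of class `count_matrix`: a list with elements
#'   `values`, `kind` and `sheet`.
#' @export
count_matrix <- function(values, kind = c("raw", "tpm", "tmm", "log2tmm"),
                         sheet) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id: ",
         rownames(values)[duplicated(rownames(values))][1L], call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample id in matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("non-finite value in expression matrix", call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value at (gene %s, sample %s)",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]),
         call. = FALSE)
  }
  missing_samples <- setdiff(colnames(values), sheet$sample_id)
  if (length(missing_samples)) {
    stop("sample not in sample sheet: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  if (kind == "tpm") {
    cs <- colSums(values)
    if (any(abs(cs - 1e6) > 1e6 * 1e-6)) {
      stop("tpm matrix columns must each sum to 1e6", call. = FALSE)
    }
  }
  sheet <- sheet[match(colnames(values), sheet$sample_id), , drop = FALSE]
  rownames(sheet) <- NULL
  structure(list(values = values, kind = kind, sheet = sheet),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d genes x %d samples, %d tissue(s)\n",
              x$kind, nrow(x$values), ncol(x$values),
              length(unique(x$sheet$tissue))))
  invisible(x)
}

#' @export
summary.count_matrix <- function(object, ...) {
  v <- object$values
  out <- data.frame(
    sample_id = colnames(v),
    tissue = object$sheet$tissue,
    total = colSums(v),
    n_nonzero = colSums(v > 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

## tissues -> named list of column indices, in sheet order of appearance
tissue_columns <- function(cm) {
  tissues <- unique(cm$sheet$tissue)
  cols <- lapply(tissues, function(t) which(cm$sheet$tissue == t))
  names(cols) <- tissues
  cols
}

## per-tissue row means of a plain matrix given a sample sheet
tissue_means <- function(values, sheet) {
  tissues <- unique(sheet$tissue)
  out <- vapply(tissues, function(t) {
    rowMeans(values[, sheet$tissue == t, drop = FALSE])
  }, numeric(nrow(values)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L,
                                       dimnames = list(rownames(values),
                                                       tissues))
  out
}
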