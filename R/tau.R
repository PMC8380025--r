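#' Expression filter preceding the tau index
#'
#' Log2-transforms a TMM matrix, declares values below `min_expression`
#' "not expressed" by flooring their log2 value to zero (equivalently,
#' all negative log2 values become 0), and removes genes expressed in
#' fewer than `min_samples_expressed` samples. The tau index considers
#' specificity independently of expression level, so this filter
#' removes genes with low support for true expression before it is
#' computed.
#'
#' @param tmm A [count_matrix()] of kind `tmm`.
#' @param min_expression TMM value below which a gene is "not expressed"
#'   in a sample (default 1, i.e. negative log2 values).
#' @param min_samples_expressed Minimum number of samples with nonzero
#'   filtered expression for a gene to be retained (default 2, i.e.
#'   genes expressed in at most one sample are excluded).
#' @return List with `matrix` (a [count_matrix()] of kind `log2tmm`
#'   restricted to retained genes) and `excluded` (character vector of
#'   removed gene ids).
#' @export
filter_for_tau <- function(tmm, min_expression = 1.0,
                           min_samples_expressed = 2L) {
  stopifnot(inherits(tmm, "count_matrix"))
  if (tmm$kind != "tmm") stop("expected a tmm matrix", call. = FALSE)
  v <- tmm$values
  lv <- suppressWarnings(log2(v))
  lv[v < min_expression] <- 0
  lv[!is.finite(lv) | lv < 0] <- 0
  n_expressed <- rowSums(lv > 0)
  keep <- n_expressed >= min_samples_expressed
  list(matrix = count_matrix(lv[keep, , drop = FALSE], kind = "log2tmm",
                             sheet = tmm$sheet),
       excluded = rownames(v)[!keep])
}

#' Compute the tau tissue-specificity index
#'
#' For each gene, per-tissue mean expression \eqn{x_i} is taken over the
#' filtered log2 values of tissue i's replicates, normalized by the
#' maximum \eqn{X_i = x_i / \max_j x_j}, and
#' \deqn{\tau = \frac{\sum_{i=1}^{N} (1 - X_i)}{N - 1}}
#' over the N tissues. tau is 0 for a gene expressed equally in all
#' tissues and 1 for a gene expressed in exactly one tissue; a gene is
#' flagged tissue-specific only when tau equals 1 exactly, i.e. every
#' non-maximum tissue mean is exactly 0 after the expression filter.
#'
#' @param filtered A [count_matrix()] of kind `log2tmm`, as produced by
#'   [filter_for_tau()]; at least two tissues required.
#' @return `data.frame` with columns `gene_id`, `tau`, `argmax_tissue`,
#'   `is_specific`, `n_expressed_samples`, plus one `mean_<tissue>`
#'   column per tissue.
#' @export
compute_tau <- function(filtered) {
  stopifnot(inherits(filtered, "count_matrix"))
  if (filtered$kind != "log2tmm") {
    stop("expected a log2tmm matrix (run filter_for_tau first)",
         call. = FALSE)
  }
  tissues <- unique(filtered$sheet$tissue)
  n_t <- length(tissues)
  if (n_t < 2L) stop("need >= 2 tissues for tau", call. = FALSE)
  means <- tissue_means(filtered$values, filtered$sheet)
  mx <- apply(means, 1L, max)
  if (any(mx <= 0)) {
    stop("gene with all-zero tissue means reached compute_tau: ",
         rownames(means)[which(mx <= 0)[1L]], call. = FALSE)
  }
  xnorm <- means / mx
  tau <- rowSums(1 - xnorm) / (n_t - 1)
  amax <- tissues[apply(means, 1L, which.max)]
  specific <- rowSums(means > 0) == 1L
  out <- data.frame(
    gene_id = rownames(means),
    tau = tau,
    argmax_tissue = amax,
    is_specific = specific,
    n_expressed_samples = as.integer(rowSums(filtered$values > 0)),
    stringsAsFactors = FALSE, row.names = NULL)
  mcols <- as.data.frame(means)
  colnames(mcols) <- paste0("mean_", tissues)
  rownames(mcols) <- NULL
  cbind(out, mcols)
}

#' Extract tissue-specific genes (tau = 1)
#'
#' @param taus A [compute_tau()] table.
#' @return List with `genes` (the rows with `is_specific = TRUE`) and
#'   `counts` (named integer vector of specific genes per tissue).
#' @export
call_specific_genes <- function(taus) {
  genes <- taus[taus$is_specific, , drop = FALSE]
  rownames(genes) <- NULL
  counts <- table(factor(genes$argmax_tissue))
  list(genes = genes,
       counts = stats::setNames(as.integer(counts), names(counts)))
}
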