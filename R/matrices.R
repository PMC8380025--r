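#' Aggregate transcript quantifications to gene-level matrices
#'
#' Sums member-transcript `NumReads` per gene to form the raw count
#' matrix and sums member-transcript TPM per gene to form the TPM
#' matrix. Each TPM column is then rescaled to sum to 1e6, restoring
#' the transcripts-per-million property after any transcript removal
#' (e.g. contaminant filtering).
#'
#' @param quants Named list of per-sample quantification tables
#'   ([read_quant_table()]); all samples must share one transcript
#'   universe.
#' @param map `data.frame` with columns `transcript_id`, `gene_id`; must
#'   cover every transcript in `quants`.
#' @param sheet A [sample_sheet()] covering the samples in `quants`.
#' @return List with elements `raw` and `tpm`, both [count_matrix()]
#'   objects with genes in map order.
#' @export
aggregate_to_genes <- function(quants, map, sheet) {
  if (is.null(names(quants)) || any(!nzchar(names(quants)))) {
    stop("quants must be a named list (names = sample ids)", call. = FALSE)
  }
  gene_levels <- unique(map$gene_id)
  ref_tx <- sort(quants[[1L]]$transcript_id)
  for (s in names(quants)) {
    q <- quants[[s]]
    if (!identical(sort(q$transcript_id), ref_tx)) {
      stop("samples do not share one transcript universe (sample ", s, ")",
           call. = FALSE)
    }
    unmapped <- setdiff(q$transcript_id, map$transcript_id)
    if (length(unmapped)) {
      stop("transcript absent from transcript-to-gene map: ",
           unmapped[1L], call. = FALSE)
    }
  }
  agg_one <- function(q, column) {
    gene <- map$gene_id[match(q$transcript_id, map$transcript_id)]
    sums <- rowsum(q[[column]], group = factor(gene, levels = gene_levels))
    sums[, 1L]
  }
  raw_v <- vapply(quants, agg_one, numeric(length(gene_levels)),
                  column = "num_reads")
  tpm_v <- vapply(quants, agg_one, numeric(length(gene_levels)),
                  column = "tpm")
  if (length(gene_levels) == 1L) {
    raw_v <- matrix(raw_v, nrow = 1L,
                    dimnames = list(gene_levels, names(quants)))
    tpm_v <- matrix(tpm_v, nrow = 1L,
                    dimnames = list(gene_levels, names(quants)))
  } else {
    rownames(raw_v) <- rownames(tpm_v) <- gene_levels
  }
  cs <- colSums(tpm_v)
  if (any(cs <= 0)) {
    stop("sample with zero total TPM: ",
         colnames(tpm_v)[which(cs <= 0)[1L]], call. = FALSE)
  }
  tpm_v <- sweep(tpm_v, 2L, cs / 1e6, "/")
  list(raw = count_matrix(raw_v, kind = "raw", sheet = sheet),
       tpm = count_matrix(tpm_v, kind = "tpm", sheet = sheet))
}

#' Scale a raw count matrix to counts-per-million
#'
#' Rescales each column of a raw count matrix to sum to 1e6. Used when
#' the pipeline starts from a bare count matrix with no transcript
#' length information; the result plays the role of the TPM-scaled
#' matrix in the downstream TMM stage.
#'
#' @param raw A [count_matrix()] of kind `raw`.
#' @return A [count_matrix()] of kind `tpm` (columns sum to 1e6).
#' @export
tpm_from_counts <- function(raw) {
  stopifnot(inherits(raw, "count_matrix"))
  if (raw$kind != "raw") stop("expected a raw count matrix", call. = FALSE)
  cs <- colSums(raw$values)
  if (any(cs <= 0)) {
    stop("sample with zero library size: ",
         colnames(raw$values)[which(cs <= 0)[1L]], call. = FALSE)
  }
  count_matrix(sweep(raw$values, 2L, cs / 1e6, "/"), kind = "tpm",
               sheet = raw$sheet)
}

#' Compute trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample scaling factors robust to composition bias. For each
#' sample against a reference sample, gene-wise log ratios
#' \eqn{M = \log_2((y_s/N_s)/(y_r/N_r))} and average log abundances
#' \eqn{A = 0.5\,\log_2((y_s/N_s)(y_r/N_r))} are computed over genes
#' with positive counts in both samples; the upper and lower `trim_m`
#' fraction by M and `trim_a` fraction by A are discarded; the factor is
#' 2 to the precision-weighted mean of the remaining M values, with
#' inverse approximate binomial variances
#' \eqn{(1/y_s - 1/N_s + 1/y_r - 1/N_r)^{-1}} as weights. Factors are
#' rescaled so their geometric mean is 1. The reference is the sample
#' whose upper quartile of scaled counts is closest to the mean upper
#' quartile.
#'
#' @param raw A [count_matrix()] of kind `raw`; every sample must have a
#'   positive library size.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return An object of class `tmm_factors`: a `data.frame` with columns
#'   `sample_id`, `library_size`, `norm_factor`.
#' @export
compute_tmm_factors <- function(raw, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(raw, "count_matrix"))
  if (raw$kind != "raw") stop("expected a raw count matrix", call. = FALSE)
  y <- raw$values
  lib <- colSums(y)
  zero <- which(lib <= 0)
  if (length(zero)) {
    stop("sample with zero library size: ", colnames(y)[zero[1L]],
         call. = FALSE)
  }
  uq <- apply(y, 2L, function(col) stats::quantile(col / sum(col), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(s) {
    if (s == ref) return(1)
    tmm_pair_factor(y[, s], y[, ref], lib[s], lib[ref], trim_m, trim_a,
                    pair = paste(colnames(y)[s], colnames(y)[ref],
                                 sep = " vs "))
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  out <- data.frame(sample_id = colnames(y), library_size = lib,
                    norm_factor = f, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tmm_factors", "data.frame")
  out
}

## single-pair TMM factor (sample s vs reference r)
tmm_pair_factor <- function(ys, yr, ns, nr, trim_m, trim_a, pair) {
  keep <- ys > 0 & yr > 0
  ys <- ys[keep]; yr <- yr[keep]
  if (!length(ys)) stop("no genes with positive counts in both samples (",
                        pair, ")", call. = FALSE)
  ps <- ys / ns; pr <- yr / nr
  m <- log2(ps / pr)
  a <- 0.5 * log2(ps * pr)
  w <- 1 / (1 / ys - 1 / ns + 1 / yr - 1 / nr)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) stop("no genes survive TMM trimming (", pair, ")",
                        call. = FALSE)
  2^(sum(w[keep2] * m[keep2]) / sum(w[keep2]))
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM normalization factors for", nrow(x), "samples",
      sprintf("(geometric mean %.6f)\n", exp(mean(log(x$norm_factor)))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Apply TMM factors to a TPM-scaled matrix
#'
#' Divides each sample column by its normalization factor, yielding the
#' TMM-normalized expression matrix used by the PUR and tau stages.
#'
#' @param tpm A [count_matrix()] of kind `tpm`.
#' @param factors A [compute_tmm_factors()] result for the same samples.
#' @return A [count_matrix()] of kind `tmm`.
#' @export
apply_tmm <- function(tpm, factors) {
  stopifnot(inherits(tpm, "count_matrix"), inherits(factors, "tmm_factors"))
  if (tpm$kind != "tpm") stop("expected a tpm matrix", call. = FALSE)
  if (!setequal(colnames(tpm$values), factors$sample_id)) {
    stop("sample mismatch between matrix and TMM factors", call. = FALSE)
  }
  f <- factors$norm_factor[match(colnames(tpm$values), factors$sample_id)]
  count_matrix(sweep(tpm$values, 2L, f, "/"), kind = "tmm",
               sheet = tpm$sheet)
}

#' Log2-transform a TMM matrix
#'
#' @param m A [count_matrix()] of kind `tmm`.
#' @param pseudocount Added before the log; the default 1 maps 0 to 0
#'   and is used on the PUR path. The tau path instead floors values
#'   below 1 to zero via [filter_for_tau()].
#' @return A [count_matrix()] of kind `log2tmm`.
#' @export
log2_transform <- function(m, pseudocount = 1.0) {
  stopifnot(inherits(m, "count_matrix"))
  if (m$kind != "tmm") stop("expected a tmm matrix", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  v <- log2(m$values + pseudocount)
  v[!is.finite(v) | v < 0] <- 0
  count_matrix(v, kind = "log2tmm", sheet = m$sheet)
}

#' Replicate-clustering quality control
#'
#' Principal component analysis and a sample-by-sample Pearson
#' correlation matrix on log2(count + 1) values, genes as variables and
#' samples as observations (centered, unscaled). A sample "clusters with
#' its own tissue" when its nearest neighbour by correlation shares its
#' tissue label.
#'
#' @param raw A [count_matrix()] of kind `raw` with at least 3 samples.
#' @return List with `pca` (samples x components coordinate matrix),
#'   `variance_explained` (per component), `correlation` (sample x
#'   sample Pearson matrix) and `clusters_with_tissue` (named logical).
#' @export
qc_replicates <- function(raw) {
  stopifnot(inherits(raw, "count_matrix"))
  v <- log2(raw$values + 1)
  if (ncol(v) < 3L) stop("need >= 3 samples for QC", call. = FALSE)
  if (all(apply(v, 1L, stats::var) == 0)) {
    stop("constant matrix: no variance for PCA", call. = FALSE)
  }
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  keep <- seq_len(max(2L, min(ncol(pc$x), 5L)))
  corr <- stats::cor(v)
  tissue <- raw$sheet$tissue
  flag <- vapply(seq_len(ncol(v)), function(s) {
    others <- setdiff(seq_len(ncol(v)), s)
    nn <- others[which.max(corr[s, others])]
    tissue[nn] == tissue[s]
  }, logical(1L))
  names(flag) <- colnames(v)
  list(pca = pc$x[, keep, drop = FALSE],
       variance_explained = (pc$sdev^2 / sum(pc$sdev^2))[keep],
       correlation = corr,
       clusters_with_tissue = flag)
}
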