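#' Estimate negative-binomial dispersion by method of moments
#'
#' For each gene within each tissue group, counts are scaled to a common
#' effective library size and a method-of-moments dispersion is solved
#' from \eqn{v = m + \phi m^2} (negative estimates floored at 0).
#' Per-gene estimates are pooled across tissues by a count-weighted
#' average; the common dispersion is a 20% trimmed mean of the per-gene
#' values; final per-gene dispersions are shrunk toward the common value
#' with weight `shrink_weight`.
#'
#' @param raw A [count_matrix()] of kind `raw`; every tissue must have
#'   at least 2 replicates.
#' @param factors Optional [compute_tmm_factors()] result; when `NULL`
#'   all normalization factors are taken as 1 and only library sizes are
#'   used.
#' @param shrink_weight Weight on the common dispersion in the per-gene
#'   estimate, in \[0, 1\].
#' @return An object of class `dispersion_estimate`: list with
#'   `common_dispersion` (scalar) and `per_gene` (named numeric).
#' @export
estimate_dispersion <- function(raw, factors = NULL, shrink_weight = 0.9) {
  stopifnot(inherits(raw, "count_matrix"))
  if (raw$kind != "raw") stop("expected a raw count matrix", call. = FALSE)
  if (shrink_weight < 0 || shrink_weight > 1) {
    stop("shrink_weight must be in [0, 1]", call. = FALSE)
  }
  y <- raw$values
  lib <- colSums(y)
  nf <- rep(1, ncol(y))
  if (!is.null(factors)) {
    nf <- factors$norm_factor[match(colnames(y), factors$sample_id)]
  }
  eff <- lib * nf
  common_size <- exp(mean(log(eff)))
  ys <- sweep(y, 2L, common_size / eff, "*")
  cols <- tissue_columns(raw)
  small <- names(cols)[vapply(cols, length, integer(1L)) < 2L]
  if (length(small)) {
    stop("tissue with < 2 replicates: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  phi_t <- matrix(NA_real_, nrow(y), length(cols))
  w_t <- matrix(0, nrow(y), length(cols))
  for (i in seq_along(cols)) {
    sub <- ys[, cols[[i]], drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, stats::var)
    phi <- ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
    phi_t[, i] <- phi
    w_t[, i] <- rowSums(sub)
  }
  w_t[is.na(phi_t)] <- 0
  phi_t[is.na(phi_t)] <- 0
  wsum <- rowSums(w_t)
  phi_g <- ifelse(wsum > 0, rowSums(phi_t * w_t) / wsum, NA_real_)
  usable <- phi_g[is.finite(phi_g)]
  if (!length(usable)) stop("no gene with positive counts", call. = FALSE)
  common <- mean(usable, trim = 0.2)
  per_gene <- shrink_weight * common + (1 - shrink_weight) * phi_g
  per_gene[!is.finite(per_gene)] <- common
  names(per_gene) <- rownames(y)
  structure(list(common_dispersion = common, per_gene = per_gene),
            class = "dispersion_estimate")
}

#' @export
print.dispersion_estimate <- function(x, ...) {
  cat(sprintf(
    "NB dispersion estimate: common %.4f, per-gene range [%.4f, %.4f]\n",
    x$common_dispersion, min(x$per_gene), max(x$per_gene)))
  invisible(x)
}

#' Exact negative-binomial test for one tissue pair
#'
#' The group-sum conditional exact test. Replicate counts are scaled to
#' the pair's common effective library size (geometric mean of library
#' size times normalization factor over the pair's samples) and rounded
#' to pseudocounts; group sums are formed; under the null of equal
#' means both group sums are negative binomial and the conditional
#' distribution of the first group's sum given the total is evaluated by
#' enumeration. The two-sided p-value sums the probabilities of all
#' outcomes no more probable than the observed one (ties within 1e-12
#' relative are included); when the total exceeds `enum_limit` the
#' enumeration is windowed and the p-value is the doubled smaller tail,
#' capped at 1. At dispersion 0 the model reduces to Poisson and the
#' conditional law is binomial.
#'
#' @param raw A [count_matrix()] of kind `raw`.
#' @param factors A [compute_tmm_factors()] result for the same samples.
#' @param disp An [estimate_dispersion()] result (or a list with a
#'   `per_gene` named vector).
#' @param tissue_a,tissue_b Tissue labels, both with >= 2 replicates.
#'   A positive `logFC` means higher expression in `tissue_a`.
#' @param logfc_pseudocount Added to the group mean normalized counts in
#'   the reported log2 fold-change (default 0.125).
#' @param enum_limit Largest pair total enumerated in full.
#' @return `data.frame` with columns `gene_id`, `tissue_a`, `tissue_b`,
#'   `logFC`, `p_value` (FDR adjustment is a separate step, see
#'   [adjust_fdr()] and [run_pairwise_de()]).
#' @export
exact_nb_test <- function(raw, factors, disp, tissue_a, tissue_b,
                          logfc_pseudocount = 0.125, enum_limit = 10000L) {
  stopifnot(inherits(raw, "count_matrix"))
  cols <- tissue_columns(raw)
  for (t in c(tissue_a, tissue_b)) {
    if (is.null(cols[[t]])) stop("tissue not in sample sheet: ", t,
                                 call. = FALSE)
    if (length(cols[[t]]) < 2L) stop("tissue with < 2 replicates: ", t,
                                     call. = FALSE)
  }
  y <- raw$values
  lib <- colSums(y)
  nf <- factors$norm_factor[match(colnames(y), factors$sample_id)]
  eff <- lib * nf
  ia <- cols[[tissue_a]]; ib <- cols[[tissue_b]]
  common <- exp(mean(log(eff[c(ia, ib)])))
  ysc <- sweep(y[, c(ia, ib), drop = FALSE], 2L,
               common / eff[c(ia, ib)], "*")
  ysc <- round(ysc)
  ra <- length(ia); rb <- length(ib)
  sa <- rowSums(ysc[, seq_len(ra), drop = FALSE])
  sb <- rowSums(ysc[, ra + seq_len(rb), drop = FALSE])
  phi <- disp$per_gene[rownames(y)]
  if (anyNA(phi)) stop("dispersion missing for some genes", call. = FALSE)
  p <- vapply(seq_len(nrow(y)), function(g) {
    nb_condsum_pvalue(sa[g], sb[g], ra, rb, phi[g], enum_limit)
  }, numeric(1L))
  logfc <- log2((sa / ra + logfc_pseudocount) /
                (sb / rb + logfc_pseudocount))
  data.frame(gene_id = rownames(y), tissue_a = tissue_a,
             tissue_b = tissue_b, logFC = logfc, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

## conditional distribution of s_a given s_a + s_b = n under H0;
## group sums of r iid NB(mu, phi) replicates are NB(r*mu, phi/r).
nb_condsum_pvalue <- function(sa, sb, ra, rb, phi, enum_limit,
                              tie_tol = 1e-12) {
  n <- sa + sb
  if (n == 0) return(1)
  mu <- n / (ra + rb)
  logpmf <- function(x, r) {
    if (phi <= 0) {
      stats::dpois(x, lambda = r * mu, log = TRUE)
    } else {
      stats::dnbinom(x, size = r / phi, mu = r * mu, log = TRUE)
    }
  }
  if (n <= enum_limit) {
    x <- 0:n
    lp <- logpmf(x, ra) + logpmf(n - x, rb)
    lp <- lp - max(lp)
    pr <- exp(lp)
    pr <- pr / sum(pr)
    obs <- pr[sa + 1L]
    return(min(1, sum(pr[pr <= obs * (1 + tie_tol)])))
  }
  ## windowed enumeration: conditional mass concentrates near n*ra/(ra+rb)
  center <- n * ra / (ra + rb)
  sdev <- sqrt(ra * (mu + phi * mu^2))
  half <- max(50 * sdev, 10)
  lo <- max(0, floor(center - half))
  hi <- min(n, ceiling(center + half))
  x <- lo:hi
  lp <- logpmf(x, ra) + logpmf(n - x, rb)
  mx <- max(lp)
  pr <- exp(lp - mx)
  norm <- sum(pr)
  pr <- pr / norm
  ## point probability of the observed outcome, valid also outside window
  obs <- exp(logpmf(sa, ra) + logpmf(n - sa, rb) - mx) / norm
  p_low <- if (sa < lo) obs else sum(pr[x <= sa])
  p_high <- if (sa > hi) obs else sum(pr[x >= sa])
  min(1, 2 * min(p_low, p_high))
}

#' Adjust p-values for multiple testing
#'
#' Step-up false-discovery-rate adjustment (Benjamini-Hochberg by
#' default; Hochberg's step-up FWER procedure behind the `method`
#' switch). Applied within one comparison family; output order matches
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"benjamini_hochberg"` or `"hochberg"`.
#' @return Adjusted values, same length and order as `p`.
#' @export
adjust_fdr <- function(p, method = c("benjamini_hochberg", "hochberg")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = if (method == "hochberg") "hochberg" else "BH")
}

#' Run the exact test over every tissue pair
#'
#' Calls [exact_nb_test()] for each unordered tissue pair (labels
#' ordered lexicographically) and adjusts p-values to FDR separately
#' within each pair's family of genes.
#'
#' @inheritParams exact_nb_test
#' @param method FDR method passed to [adjust_fdr()].
#' @return `data.frame` with one row per (gene, tissue pair): `gene_id`,
#'   `tissue_a`, `tissue_b`, `logFC`, `p_value`, `fdr`.
#' @export
run_pairwise_de <- function(raw, factors, disp,
                            logfc_pseudocount = 0.125,
                            enum_limit = 10000L,
                            method = "benjamini_hochberg") {
  tissues <- sort(unique(raw$sheet$tissue))
  if (length(tissues) < 2L) stop("need >= 2 tissues", call. = FALSE)
  pairs <- utils::combn(tissues, 2L)
  out <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    de <- exact_nb_test(raw, factors, disp, pairs[1L, j], pairs[2L, j],
                        logfc_pseudocount = logfc_pseudocount,
                        enum_limit = enum_limit)
    de$fdr <- adjust_fdr(de$p_value, method = method)
    out[[j]] <- de
  }
  do.call(rbind, out)
}

#' Classify tissue preferentially upregulated (PUR) genes
#'
#' A gene is PUR in tissue t when, against every other tissue u, the
#' pairwise exact test reaches `fdr <= fdr_threshold` and the mean
#' log2(TMM + 1) expression in t exceeds that in u. The reported
#' fold-change is the TMM-based difference; the PUR decision uses only
#' its sign together with the FDR condition.
#'
#' @param de Pairwise DE table from [run_pairwise_de()], covering every
#'   tissue pair.
#' @param tmm A [count_matrix()] of kind `tmm` on the same genes.
#' @param fdr_threshold Maximum FDR per comparison (default 0.05).
#' @param log2_pseudocount Added before the log2 of the TMM means path
#'   (default 1).
#' @return `data.frame` with one row per (gene, tissue): `gene_id`,
#'   `tissue`, `n_comparisons_passed`, `is_pur`, `min_logfc_tmm` (the
#'   smallest TMM-based log difference against any other tissue).
#' @export
classify_pur <- function(de, tmm, fdr_threshold = 0.05,
                         log2_pseudocount = 1.0) {
  stopifnot(inherits(tmm, "count_matrix"))
  if (tmm$kind != "tmm") stop("expected a tmm matrix", call. = FALSE)
  tissues <- sort(unique(tmm$sheet$tissue))
  genes <- rownames(tmm$values)
  want <- utils::combn(tissues, 2L)
  have <- unique(paste(de$tissue_a, de$tissue_b, sep = "\r"))
  need <- paste(want[1L, ], want[2L, ], sep = "\r")
  if (!all(need %in% have)) {
    miss <- need[!(need %in% have)][1L]
    stop("DE rows missing for tissue pair: ", gsub("\r", " vs ", miss),
         call. = FALSE)
  }
  lv <- log2(tmm$values + log2_pseudocount)
  means <- tissue_means(lv, tmm$sheet)[, tissues, drop = FALSE]
  ## fdr lookup: matrix genes x pair key
  key <- paste(de$tissue_a, de$tissue_b, sep = "\r")
  fdr_lut <- lapply(split(seq_len(nrow(de)), key), function(idx) {
    stats::setNames(de$fdr[idx], de$gene_id[idx])
  })
  res <- vector("list", length(tissues))
  for (ti in seq_along(tissues)) {
    t <- tissues[ti]
    others <- setdiff(tissues, t)
    passed <- matrix(FALSE, length(genes), length(others))
    diffs <- matrix(NA_real_, length(genes), length(others))
    for (ui in seq_along(others)) {
      u <- others[ui]
      k <- if (t < u) paste(t, u, sep = "\r") else paste(u, t, sep = "\r")
      fdr_u <- fdr_lut[[k]][genes]
      if (anyNA(fdr_u)) stop("DE rows missing for some genes in pair ",
                             gsub("\r", " vs ", k), call. = FALSE)
      d <- means[, t] - means[, u]
      diffs[, ui] <- d
      passed[, ui] <- fdr_u <= fdr_threshold & d > 0
    }
    n_pass <- rowSums(passed)
    res[[ti]] <- data.frame(
      gene_id = genes, tissue = t,
      n_comparisons_passed = as.integer(n_pass),
      is_pur = n_pass == length(others),
      min_logfc_tmm = apply(diffs, 1L, min),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, res)
}
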