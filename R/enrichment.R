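#' Build the annotated background universe for enrichment
#'
#' Restricts the background to genes that carry at least one GO
#' annotation, optionally collapses genes sharing one annotation
#' identifier (e.g. the same UniProt hit, which would otherwise inflate
#' term counts through uncollapsed isoforms or gene families) to a
#' single representative, and tabulates the background gene set of each
#' GO term on the collapsed universe.
#'
#' @param gene2go Named list, gene id -> character vector of GO ids (see
#'   [read_gene2go()]).
#' @param background_ids Character vector of background gene ids.
#' @param gene2annot Optional named character vector, gene id ->
#'   annotation id, used for the unique-identifier collapse.
#' @return List with `term_genes` (term -> character vector of
#'   background genes), `background` (collapsed annotated background
#'   ids), `size` (its length) and `representative` (named vector
#'   mapping each annotated input gene to its representative).
#' @export
build_annotation_universe <- function(gene2go, background_ids,
                                      gene2annot = NULL) {
  if (!length(background_ids)) {
    stop("background_ids must be non-empty", call. = FALSE)
  }
  background_ids <- unique(as.character(background_ids))
  annotated <- background_ids[background_ids %in% names(gene2go)]
  if (!length(annotated)) {
    stop("no annotated gene in the background", call. = FALSE)
  }
  representative <- stats::setNames(annotated, annotated)
  if (!is.null(gene2annot)) {
    aid <- gene2annot[annotated]
    has <- !is.na(aid)
    first <- annotated[has][!duplicated(aid[has])]
    lut <- stats::setNames(first, aid[has][!duplicated(aid[has])])
    representative[has] <- lut[aid[has]]
  }
  universe <- unique(unname(representative))
  gene <- rep(unname(representative), lengths(gene2go[annotated]))
  term <- unlist(gene2go[annotated], use.names = FALSE)
  keep <- !duplicated(paste(gene, term, sep = "\r"))
  term_genes <- split(gene[keep], term[keep])
  list(term_genes = term_genes, background = universe,
       size = length(universe), representative = representative)
}

#' Hypergeometric singular enrichment analysis
#'
#' Tests each GO term for over-representation in a study gene set
#' against the annotated background: with N annotated background genes,
#' K of them carrying the term, and an annotated study set of size n
#' containing k term genes, the p-value is the upper-tail
#' hypergeometric probability P(X >= k). Terms with fewer than
#' `min_mapping_entries` background genes are not tested. P-values are
#' adjusted by a step-up procedure across all tested terms.
#'
#' @param study_ids Character vector of study-set gene ids (a subset of
#'   the background; unannotated genes are ignored).
#' @param universe A [build_annotation_universe()] result.
#' @param min_mapping_entries Minimum background genes per term
#'   (default 5).
#' @param alpha Significance level on the adjusted value (default 0.05).
#' @param method Adjustment passed to [adjust_fdr()]
#'   (Benjamini-Hochberg by default, Hochberg step-up as alternative).
#' @return `data.frame` ordered by p-value with columns `term`, `k`,
#'   `n`, `K`, `N_bg`, `p_value`, `fdr`, `significant`.
#' @export
run_sea <- function(study_ids, universe, min_mapping_entries = 5L,
                    alpha = 0.05, method = "benjamini_hochberg") {
  study <- unique(as.character(study_ids))
  extra <- setdiff(study, names(universe$representative))
  study <- unique(unname(universe$representative[setdiff(study, extra)]))
  empty <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N_bg = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (!length(study)) {
    warning("study set has no annotated gene; empty enrichment table")
    return(empty)
  }
  n <- length(study)
  sizes <- lengths(universe$term_genes)
  terms <- names(sizes)[sizes >= min_mapping_entries]
  if (!length(terms)) return(empty)
  k <- vapply(universe$term_genes[terms], function(g) {
    sum(g %in% study)
  }, integer(1L))
  K <- unname(sizes[terms])
  N <- universe$size
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  fdr <- adjust_fdr(p, method = method)
  out <- data.frame(term = terms, k = as.integer(k), n = n,
                    K = as.integer(K), N_bg = N, p_value = p, fdr = fdr,
                    significant = fdr <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Summarize enrichment tables
#'
#' @param tables Named list of [run_sea()] tables (e.g. one per tissue
#'   and gene-set kind).
#' @return `data.frame` with columns `set`, `n_tested`, `n_significant`.
#' @export
summarize_enrichment <- function(tables) {
  out <- data.frame(
    set = names(tables),
    n_tested = vapply(tables, nrow, integer(1L)),
    n_significant = vapply(tables, function(x) sum(x$significant),
                           integer(1L)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
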