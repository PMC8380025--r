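#' Configuration for the multi-tissue count simulator
#'
#' Defaults emulate a five-tissue, six-replicate bulk RNA-seq design at
#' desk scale: 2000 genes with log-normal baseline abundance, gamma
#' gene-wise dispersion (mean 0.2), unequal library sizes, 50 planted
#' tissue-exclusive genes and 40 planted 8-fold upregulated genes per
#' tissue, and a GO annotation with one planted over-represented term
#' per tissue.
#'
#' @param n_tissues Number of tissues (>= 2; the default 5 uses the
#'   labels embryo, megagametophyte, needle, phloem, bud).
#' @param n_replicates Biological replicates per tissue (>= 2).
#' @param n_genes Number of genes.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of
#'   the relative gene abundance.
#' @param dispersion_shape,dispersion_rate Gamma parameters of the
#'   gene-wise NB dispersion.
#' @param library_size_range Length-2 numeric, uniform range of expected
#'   library sizes.
#' @param n_specific_per_tissue Planted tissue-exclusive genes per
#'   tissue (hard zeros elsewhere).
#' @param n_pur_per_tissue Planted tissue-upregulated genes per tissue.
#' @param pur_fold_change Fold change applied to planted upregulated
#'   genes in their home tissue (> 1).
#' @param specific_expression_floor Minimum relative abundance of a
#'   planted exclusive gene in its home tissue, on the baseline scale
#'   (keeps it safely above the "not expressed" filter).
#' @param specific_leakage Fraction of home-tissue abundance leaked
#'   into the other tissues for planted exclusive genes (default 0 =
#'   hard zeros).
#' @param go_n_terms Number of background GO terms.
#' @param go_planted_terms Planted over-represented GO terms per tissue.
#' @param go_planted_coverage Fraction of a tissue's planted genes that
#'   carry its planted term(s).
#' @param go_background_terms_per_gene Mean number of random background
#'   terms per gene (Poisson).
#' @param seed Integer seed; the simulator is deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tissues = 5L, n_replicates = 6L, n_genes = 2000L,
                       baseline_log_mean = 0, baseline_log_sd = 1,
                       dispersion_shape = 2, dispersion_rate = 10,
                       library_size_range = c(1e5, 3e5),
                       n_specific_per_tissue = 50L,
                       n_pur_per_tissue = 40L,
                       pur_fold_change = 8,
                       specific_expression_floor = 1.0,
                       specific_leakage = 0,
                       go_n_terms = 200L,
                       go_planted_terms = 1L,
                       go_planted_coverage = 0.8,
                       go_background_terms_per_gene = 2,
                       seed = 1L) {
  cfg <- list(n_tissues = as.integer(n_tissues),
              n_replicates = as.integer(n_replicates),
              n_genes = as.integer(n_genes),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion_shape = dispersion_shape,
              dispersion_rate = dispersion_rate,
              library_size_range = as.numeric(library_size_range),
              n_specific_per_tissue = as.integer(n_specific_per_tissue),
              n_pur_per_tissue = as.integer(n_pur_per_tissue),
              pur_fold_change = pur_fold_change,
              specific_expression_floor = specific_expression_floor,
              specific_leakage = specific_leakage,
              go_n_terms = as.integer(go_n_terms),
              go_planted_terms = as.integer(go_planted_terms),
              go_planted_coverage = go_planted_coverage,
              go_background_terms_per_gene = go_background_terms_per_gene,
              seed = as.integer(seed))
  if (cfg$n_tissues < 2L) stop("n_tissues must be >= 2", call. = FALSE)
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2",
                                  call. = FALSE)
  per <- cfg$n_specific_per_tissue + cfg$n_pur_per_tissue
  if (per * cfg$n_tissues > cfg$n_genes) {
    stop("planted genes exceed n_genes", call. = FALSE)
  }
  if (cfg$pur_fold_change <= 1) stop("pur_fold_change must be > 1",
                                     call. = FALSE)
  pos <- c(cfg$dispersion_shape, cfg$dispersion_rate,
           cfg$library_size_range, cfg$specific_expression_floor)
  if (any(pos <= 0)) stop("scale parameters must be positive",
                          call. = FALSE)
  if (cfg$specific_leakage < 0 || cfg$specific_leakage >= 1) {
    stop("specific_leakage must be in [0, 1)", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("sim_config: %d tissues x %d replicates, %d genes ",
           "(%d specific + %d PUR planted per tissue, fold %.1f), seed %d\n"),
    x$n_tissues, x$n_replicates, x$n_genes, x$n_specific_per_tissue,
    x$n_pur_per_tissue, x$pur_fold_change, x$seed))
  invisible(x)
}

sim_tissue_labels <- function(n) {
  if (n == 5L) c("bud", "embryo", "megagametophyte", "needle", "phloem")
  else sprintf("tissue%02d", seq_len(n))
}

#' Simulate a multi-tissue negative-binomial count dataset
#'
#' Draws a log-normal relative abundance per gene, plants
#' tissue-exclusive genes (zero abundance outside the home tissue) and
#' tissue-upregulated genes (abundance multiplied by
#' `pur_fold_change` in the home tissue), draws gamma gene-wise
#' dispersions and uniform library sizes, and samples counts
#' \eqn{y_{gs} \sim NB(L_s\, q_{g,t(s)},\ \phi_g)} where the
#' per-tissue abundance columns are normalized to sum to 1. A GO
#' annotation is generated alongside, with the planted terms
#' over-represented among each tissue's planted genes.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts` (raw [count_matrix()]), `sheet`
#'   ([sample_sheet()]), `truth` (`data.frame`: `gene_id`, `role` in
#'   null/specific/pur, `tissue`, `fold_change`, `planted_term`),
#'   `gene2go` (named list), `planted_terms` (named by tissue) and
#'   `config`.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tissues <- sim_tissue_labels(cfg$n_tissues)
  n_samples <- cfg$n_tissues * cfg$n_replicates
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  sheet <- sample_sheet(
    sample_id = paste0(rep(tissues, each = cfg$n_replicates), "_r",
                       rep(seq_len(cfg$n_replicates), cfg$n_tissues)),
    tissue = rep(tissues, each = cfg$n_replicates),
    replicate = rep(sprintf("r%d", seq_len(cfg$n_replicates)),
                    cfg$n_tissues))

  q0 <- stats::rlnorm(cfg$n_genes, cfg$baseline_log_mean,
                      cfg$baseline_log_sd)
  phi <- stats::rgamma(cfg$n_genes, shape = cfg$dispersion_shape,
                       rate = cfg$dispersion_rate)
  per <- cfg$n_specific_per_tissue + cfg$n_pur_per_tissue
  planted_idx <- sample.int(cfg$n_genes, per * cfg$n_tissues)

  role <- rep("null", cfg$n_genes)
  home <- rep(NA_character_, cfg$n_genes)
  fold <- rep(NA_real_, cfg$n_genes)
  ## per-tissue abundance matrix (genes x tissues)
  q <- matrix(q0, cfg$n_genes, cfg$n_tissues,
              dimnames = list(genes, tissues))
  off <- 0L
  for (t in tissues) {
    spec <- planted_idx[off + seq_len(cfg$n_specific_per_tissue)]
    off <- off + cfg$n_specific_per_tissue
    pur <- planted_idx[off + seq_len(cfg$n_pur_per_tissue)]
    off <- off + cfg$n_pur_per_tissue
    role[spec] <- "specific"; home[spec] <- t
    role[pur] <- "pur"; home[pur] <- t
    fold[pur] <- cfg$pur_fold_change
    qs <- pmax(q0[spec], cfg$specific_expression_floor)
    q[spec, ] <- cfg$specific_leakage * qs
    q[spec, t] <- qs
    q[pur, t] <- q0[pur] * cfg$pur_fold_change
  }
  q <- sweep(q, 2L, colSums(q), "/")

  lib <- stats::runif(n_samples, cfg$library_size_range[1L],
                      cfg$library_size_range[2L])
  values <- matrix(0, cfg$n_genes, n_samples,
                   dimnames = list(genes, sheet$sample_id))
  for (s in seq_len(n_samples)) {
    mu <- lib[s] * q[, sheet$tissue[s]]
    values[, s] <- ifelse(mu == 0, 0,
                          stats::rnbinom(cfg$n_genes, mu = mu,
                                         size = 1 / phi))
  }

  ## GO annotation: background terms uniform, planted terms on planted
  ## genes at the configured coverage plus a thin background rate
  n_bg_terms <- cfg$go_n_terms
  n_pl_terms <- cfg$go_planted_terms * cfg$n_tissues
  all_terms <- sprintf("GO:%07d", seq_len(n_bg_terms + n_pl_terms))
  bg_terms <- all_terms[seq_len(n_bg_terms)]
  pl_terms <- matrix(all_terms[n_bg_terms + seq_len(n_pl_terms)],
                     nrow = cfg$go_planted_terms,
                     dimnames = list(NULL, tissues))
  gene2go <- vector("list", cfg$n_genes)
  names(gene2go) <- genes
  n_terms_per_gene <- stats::rpois(cfg$n_genes,
                                   cfg$go_background_terms_per_gene)
  for (g in seq_len(cfg$n_genes)) {
    tg <- if (n_terms_per_gene[g] > 0) {
      sample(bg_terms, min(n_terms_per_gene[g], n_bg_terms))
    } else character(0)
    gene2go[[g]] <- tg
  }
  planted_term_of <- rep(NA_character_, cfg$n_genes)
  for (t in tissues) {
    tp <- which(role != "null" & home == t)
    carriers <- tp[stats::runif(length(tp)) < cfg$go_planted_coverage]
    for (g in carriers) {
      gene2go[[g]] <- unique(c(gene2go[[g]], pl_terms[, t]))
      planted_term_of[g] <- pl_terms[1L, t]
    }
    ## thin background presence so planted terms exist off-target too
    others <- which(role == "null")
    extra <- others[stats::runif(length(others)) < 0.01]
    for (g in extra) gene2go[[g]] <- unique(c(gene2go[[g]], pl_terms[1L, t]))
  }
  gene2go <- gene2go[lengths(gene2go) > 0]

  truth <- data.frame(gene_id = genes, role = role, tissue = home,
                      fold_change = fold,
                      planted_term = planted_term_of,
                      stringsAsFactors = FALSE)
  list(counts = count_matrix(values, kind = "raw", sheet = sheet),
       sheet = sheet, truth = truth, gene2go = gene2go,
       planted_terms = stats::setNames(pl_terms[1L, ], tissues),
       config = cfg)
}

#' Simulate per-sample transcript quantification tables
#'
#' Runs [simulate_counts()] and splits each gene's counts across
#' isoforms by a gene-wise Dirichlet draw (shared across samples), so
#' that summing isoform `NumReads` per gene reproduces the simulated
#' gene count matrix exactly. Transcript lengths are drawn uniformly;
#' per-sample TPM is computed from reads and effective lengths and sums
#' to 1e6.
#'
#' @param cfg A [sim_config()].
#' @param isoforms_per_gene Number of isoforms per gene (>= 1).
#' @return List with `quants` (named list of quantification
#'   `data.frame`s), `map` (`transcript_id`, `gene_id`) and `sim` (the
#'   [simulate_counts()] result).
#' @export
simulate_quant_files <- function(cfg, isoforms_per_gene = 3L) {
  isoforms_per_gene <- as.integer(isoforms_per_gene)
  if (isoforms_per_gene < 1L) stop("isoforms_per_gene must be >= 1",
                                   call. = FALSE)
  sim <- simulate_counts(cfg)
  values <- sim$counts$values
  genes <- rownames(values)
  n_tx <- length(genes) * isoforms_per_gene
  tx_gene <- rep(genes, each = isoforms_per_gene)
  tx_id <- paste0(tx_gene, "_i",
                  rep(seq_len(isoforms_per_gene), length(genes)))
  ## gene-wise isoform usage, shared across samples
  w <- matrix(stats::rgamma(n_tx, shape = 1), ncol = isoforms_per_gene,
              byrow = TRUE)
  w <- w / rowSums(w)
  len <- round(stats::runif(n_tx, 400, 3000))
  efflen <- pmax(len - 150, 25)
  quants <- lapply(colnames(values), function(s) {
    reads <- as.vector(t(values[, s] * w))
    rate <- reads / efflen
    denom <- sum(rate)
    tpm <- if (denom > 0) rate / denom * 1e6 else rep(0, n_tx)
    data.frame(transcript_id = tx_id, length = len,
               effective_length = efflen, tpm = tpm, num_reads = reads,
               stringsAsFactors = FALSE)
  })
  names(quants) <- colnames(values)
  list(quants = quants,
       map = data.frame(transcript_id = tx_id, gene_id = tx_gene,
                        stringsAsFactors = FALSE),
       sim = sim)
}
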