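#' Pipeline configuration
#'
#' Collects every stage parameter with the analysis defaults: FDR 0.05
#' for differential expression, TMM values below 1 treated as not
#' expressed, genes expressed in at most one sample excluded from tau,
#' at least five mapping entries per GO term, and enrichment
#' significance 0.05.
#'
#' @param fdr_threshold Maximum per-comparison FDR for PUR calls.
#' @param min_expression "Not expressed" threshold on TMM values.
#' @param min_samples_expressed Minimum expressed samples for tau.
#' @param min_mapping_entries Minimum background genes per GO term.
#' @param alpha Enrichment significance level on the adjusted value.
#' @param trim_m,trim_a TMM trim fractions.
#' @param shrink_weight Dispersion shrinkage weight.
#' @param logfc_pseudocount Pseudocount in the exact test's reported
#'   fold-change.
#' @param log2_pseudocount Pseudocount in the log2 TMM means used for
#'   the PUR sign.
#' @param enum_limit Full-enumeration cap of the exact test.
#' @param seed Seed forwarded to the simulator.
#' @param sim A [sim_config()] used by the `simulate` stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_threshold = 0.05, min_expression = 1.0,
                            min_samples_expressed = 2L,
                            min_mapping_entries = 5L, alpha = 0.05,
                            trim_m = 0.30, trim_a = 0.05,
                            shrink_weight = 0.9,
                            logfc_pseudocount = 0.125,
                            log2_pseudocount = 1.0,
                            enum_limit = 10000L,
                            seed = 1L,
                            sim = sim_config(seed = seed)) {
  cfg <- list(fdr_threshold = fdr_threshold,
              min_expression = min_expression,
              min_samples_expressed = as.integer(min_samples_expressed),
              min_mapping_entries = as.integer(min_mapping_entries),
              alpha = alpha, trim_m = trim_m, trim_a = trim_a,
              shrink_weight = shrink_weight,
              logfc_pseudocount = logfc_pseudocount,
              log2_pseudocount = log2_pseudocount,
              enum_limit = as.integer(enum_limit),
              seed = as.integer(seed), sim = sim)
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_path <- function(outdir, name) file.path(outdir, name)

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], as.character)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run one pipeline stage
#'
#' Stages communicate only through TSV files under `outdir`:
#' \describe{
#'   \item{simulate}{writes `counts.tsv`, `sample_sheet.tsv`,
#'     `truth.tsv`, `gene2go.tsv`.}
#'   \item{matrices}{reads the raw counts, writes `tpm.tsv`,
#'     `tmm_factors.tsv`, `tmm.tsv`, `qc_pca.tsv`,
#'     `qc_correlation.tsv`.}
#'   \item{de}{writes the pairwise exact-test table `de.tsv`.}
#'   \item{pur}{writes `pur.tsv`.}
#'   \item{tau}{writes `tau.tsv` and `specific.tsv`.}
#'   \item{enrich}{writes `enrichment_<set>_<tissue>.tsv` per tissue for
#'     both the PUR and the specific gene sets, and
#'     `enrichment_summary.tsv`.}
#'   \item{all}{all of the above plus `run_summary.tsv`.}
#' }
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @param outdir Output (and input) directory; created if missing.
#' @return Invisibly, a named list of the stage's in-memory results.
#' @export
run_stage <- function(name = c("simulate", "matrices", "de", "pur",
                               "tau", "enrich", "all"),
                      config = pipeline_config(), outdir) {
  name <- match.arg(name)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  switch(name,
         simulate = stage_simulate(config, outdir),
         matrices = stage_matrices(config, outdir),
         de = stage_de(config, outdir),
         pur = stage_pur(config, outdir),
         tau = stage_tau(config, outdir),
         enrich = stage_enrich(config, outdir),
         all = run_pipeline(config, outdir))
}

#' Run the full pipeline on a simulated dataset
#'
#' Equivalent to `run_stage("all", ...)`: simulate, build matrices,
#' pairwise DE, PUR classification, tau, enrichment, and a
#' machine-readable run summary.
#'
#' @inheritParams run_stage
#' @return Invisibly, a named list with every stage result plus
#'   `summary` (the run-summary `data.frame`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  sim <- stage_simulate(config, outdir)
  mats <- stage_matrices(config, outdir)
  de <- stage_de(config, outdir)
  pur <- stage_pur(config, outdir)
  tau <- stage_tau(config, outdir)
  enr <- stage_enrich(config, outdir)
  pur_tab <- pur$pur
  spec_counts <- tau$specific$counts
  tissues <- sort(unique(sim$sheet$tissue))
  summary_rows <- data.frame(
    key = c("genes_in",
            "genes_after_tau_filter",
            paste0("pur_", tissues),
            paste0("specific_", tissues),
            "significant_terms_total"),
    value = c(nrow(sim$counts$values),
              nrow(tau$filtered$matrix$values),
              vapply(tissues, function(t) {
                sum(pur_tab$is_pur & pur_tab$tissue == t)
              }, numeric(1L)),
              vapply(tissues, function(t) {
                if (t %in% names(spec_counts)) spec_counts[[t]] else 0
              }, numeric(1L)),
              sum(enr$summary$n_significant)),
    stringsAsFactors = FALSE)
  write_tsv(summary_rows, pipeline_path(outdir, "run_summary.tsv"))
  invisible(list(sim = sim, matrices = mats, de = de, pur = pur,
                 tau = tau, enrichment = enr, summary = summary_rows))
}

stage_simulate <- function(config, outdir) {
  sim <- simulate_counts(config$sim)
  write_count_matrix(sim$counts, pipeline_path(outdir, "counts.tsv"))
  write_tsv(as.data.frame(sim$sheet),
            pipeline_path(outdir, "sample_sheet.tsv"))
  write_tsv(sim$truth, pipeline_path(outdir, "truth.tsv"))
  write_gene2go(sim$gene2go, pipeline_path(outdir, "gene2go.tsv"))
  invisible(sim)
}

load_counts <- function(outdir) {
  sheet <- read_sample_sheet(pipeline_path(outdir, "sample_sheet.tsv"))
  read_count_matrix(pipeline_path(outdir, "counts.tsv"), sheet, "raw")
}

require_inputs <- function(outdir, files) {
  paths <- vapply(files, pipeline_path, character(1L), outdir = outdir)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    stop("missing pipeline input(s) in ", outdir, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

stage_matrices <- function(config, outdir) {
  require_inputs(outdir, c("counts.tsv", "sample_sheet.tsv"))
  raw <- load_counts(outdir)
  tpm <- tpm_from_counts(raw)
  factors <- compute_tmm_factors(raw, trim_m = config$trim_m,
                                 trim_a = config$trim_a)
  tmm <- apply_tmm(tpm, factors)
  qc <- qc_replicates(raw)
  write_count_matrix(tpm, pipeline_path(outdir, "tpm.tsv"))
  write_tsv(as.data.frame(factors),
            pipeline_path(outdir, "tmm_factors.tsv"))
  write_count_matrix(tmm, pipeline_path(outdir, "tmm.tsv"))
  pca_df <- data.frame(sample_id = rownames(qc$pca),
                       as.data.frame(qc$pca),
                       clusters_with_tissue = qc$clusters_with_tissue,
                       stringsAsFactors = FALSE)
  write_tsv(pca_df, pipeline_path(outdir, "qc_pca.tsv"))
  corr_df <- data.frame(sample_id = rownames(qc$correlation),
                        as.data.frame(qc$correlation),
                        stringsAsFactors = FALSE)
  write_tsv(corr_df, pipeline_path(outdir, "qc_correlation.tsv"))
  invisible(list(raw = raw, tpm = tpm, factors = factors, tmm = tmm,
                 qc = qc))
}

load_factors <- function(outdir) {
  tab <- utils::read.delim(pipeline_path(outdir, "tmm_factors.tsv"),
                           stringsAsFactors = FALSE)
  class(tab) <- c("tmm_factors", "data.frame")
  tab
}

stage_de <- function(config, outdir) {
  require_inputs(outdir, c("counts.tsv", "sample_sheet.tsv",
                           "tmm_factors.tsv"))
  raw <- load_counts(outdir)
  factors <- load_factors(outdir)
  disp <- estimate_dispersion(raw, factors,
                              shrink_weight = config$shrink_weight)
  de <- run_pairwise_de(raw, factors, disp,
                        logfc_pseudocount = config$logfc_pseudocount,
                        enum_limit = config$enum_limit)
  write_tsv(de, pipeline_path(outdir, "de.tsv"))
  invisible(list(disp = disp, de = de))
}

load_tmm <- function(outdir) {
  sheet <- read_sample_sheet(pipeline_path(outdir, "sample_sheet.tsv"))
  read_count_matrix(pipeline_path(outdir, "tmm.tsv"), sheet, "tmm")
}

stage_pur <- function(config, outdir) {
  require_inputs(outdir, c("de.tsv", "tmm.tsv", "sample_sheet.tsv"))
  de <- utils::read.delim(pipeline_path(outdir, "de.tsv"),
                          stringsAsFactors = FALSE)
  tmm <- load_tmm(outdir)
  pur <- classify_pur(de, tmm, fdr_threshold = config$fdr_threshold,
                      log2_pseudocount = config$log2_pseudocount)
  write_tsv(pur, pipeline_path(outdir, "pur.tsv"))
  invisible(list(pur = pur))
}

stage_tau <- function(config, outdir) {
  require_inputs(outdir, c("tmm.tsv", "sample_sheet.tsv"))
  tmm <- load_tmm(outdir)
  filtered <- filter_for_tau(tmm, min_expression = config$min_expression,
                             min_samples_expressed =
                               config$min_samples_expressed)
  taus <- compute_tau(filtered$matrix)
  specific <- call_specific_genes(taus)
  write_tsv(taus, pipeline_path(outdir, "tau.tsv"))
  write_tsv(specific$genes, pipeline_path(outdir, "specific.tsv"))
  invisible(list(filtered = filtered, tau = taus, specific = specific))
}

stage_enrich <- function(config, outdir) {
  require_inputs(outdir, c("pur.tsv", "tau.tsv", "specific.tsv",
                           "gene2go.tsv", "counts.tsv",
                           "sample_sheet.tsv"))
  gene2go <- read_gene2go(pipeline_path(outdir, "gene2go.tsv"))
  raw <- load_counts(outdir)
  pur <- utils::read.delim(pipeline_path(outdir, "pur.tsv"),
                           stringsAsFactors = FALSE)
  taus <- utils::read.delim(pipeline_path(outdir, "tau.tsv"),
                            stringsAsFactors = FALSE)
  specific <- utils::read.delim(pipeline_path(outdir, "specific.tsv"),
                                stringsAsFactors = FALSE)
  tissues <- sort(unique(raw$sheet$tissue))
  ## PUR background: all genes in the raw matrix; specific background:
  ## genes surviving the tau filter
  uni_pur <- build_annotation_universe(gene2go, rownames(raw$values))
  uni_tau <- build_annotation_universe(gene2go, taus$gene_id)
  tables <- list()
  for (t in tissues) {
    study_pur <- pur$gene_id[pur$is_pur & pur$tissue == t]
    study_spec <- specific$gene_id[specific$argmax_tissue == t]
    tables[[paste0("pur_", t)]] <-
      suppressWarnings(run_sea(study_pur, uni_pur,
                               min_mapping_entries =
                                 config$min_mapping_entries,
                               alpha = config$alpha))
    tables[[paste0("specific_", t)]] <-
      suppressWarnings(run_sea(study_spec, uni_tau,
                               min_mapping_entries =
                                 config$min_mapping_entries,
                               alpha = config$alpha))
  }
  for (nm in names(tables)) {
    write_tsv(tables[[nm]],
              pipeline_path(outdir, paste0("enrichment_", nm, ".tsv")))
  }
  summ <- summarize_enrichment(tables)
  write_tsv(summ, pipeline_path(outdir, "enrichment_summary.tsv"))
  invisible(list(tables = tables, summary = summ))
}
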