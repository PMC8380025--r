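## Shared fixture builders; all data is generated in code.

## genes x samples matrix -> count_matrix with a two-or-more-tissue sheet
fix_matrix <- function(values, tissues, kind = "raw") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  reps <- unlist(lapply(table(factor(tissues, levels = unique(tissues))),
                        function(k) paste0("r", seq_len(k))),
                 use.names = FALSE)
  count_matrix(values, kind,
               sample_sheet(colnames(values), tissues, reps))
}

## NB count matrix with two groups of r replicates each
fix_nb_two_group <- function(n_genes, r, mu, phi, seed,
                             fold = 1, n_up = 0) {
  set.seed(seed)
  base <- stats::rlnorm(n_genes, log(mu), 1)
  mu_a <- base
  if (n_up > 0) mu_a[seq_len(n_up)] <- base[seq_len(n_up)] * fold
  draw <- function(m) {
    if (phi == 0) stats::rpois(n_genes * r, rep(m, r))
    else stats::rnbinom(n_genes * r, mu = rep(m, r), size = 1 / phi)
  }
  y <- cbind(matrix(draw(mu_a), n_genes), matrix(draw(base), n_genes))
  rownames(y) <- sprintf("g%04d", seq_len(n_genes))
  colnames(y) <- c(paste0("a", seq_len(r)), paste0("b", seq_len(r)))
  fix_matrix(y, rep(c("a", "b"), each = r))
}

fix_unit_factors <- function(cm) {
  out <- data.frame(sample_id = colnames(cm$values),
                    library_size = colSums(cm$values),
                    norm_factor = 1, stringsAsFactors = FALSE)
  class(out) <- c("tmm_factors", "data.frame")
  out
}

fix_constant_dispersion <- function(cm, phi) {
  structure(list(common_dispersion = phi,
                 per_gene = stats::setNames(rep(phi, nrow(cm$values)),
                                            rownames(cm$values))),
            class = "dispersion_estimate")
}

## direct evaluation of the tau formula, independent of compute_tau
tau_oracle <- function(x) sum(1 - x / max(x)) / (length(x) - 1)

## write a quant table fixture and return its path
fix_quant_file <- function(rows, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  path <- file.path(dir, "quant.sf")
  writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads", rows), path)
  path
}
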