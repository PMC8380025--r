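#' Read a per-sample transcript quantification table
#'
#' Parses a tab-separated quantification table in the Salmon `quant.sf`
#' column convention (`Name`, `Length`, `EffectiveLength`, `TPM`,
#' `NumReads`, in any column order). Parsing is strict: a missing column,
#' a negative value or a duplicated transcript id is an error that names
#' the offending column or line.
#'
#' @param path Path to the tab-separated file. The first line must be a
#'   header naming the five columns.
#' @return A `data.frame` with columns `transcript_id`, `length`,
#'   `effective_length`, `tpm`, `num_reads`, rows in file order.
#' @export
read_quant_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols)) {
    stop("quant table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    transcript_id = tab$Name,
    length = as.numeric(tab$Length),
    effective_length = as.numeric(tab$EffectiveLength),
    tpm = as.numeric(tab$TPM),
    num_reads = as.numeric(tab$NumReads),
    stringsAsFactors = FALSE
  )
  num_cols <- c("length", "effective_length", "tpm", "num_reads")
  for (cn in num_cols) {
    bad <- which(!is.finite(out[[cn]]) | out[[cn]] < 0)
    if (length(bad)) {
      stop(sprintf("invalid %s at line %d of %s", cn, bad[1L] + 1L, path),
           call. = FALSE)
    }
  }
  bad <- which(out$num_reads > 0 & out$effective_length <= 0)
  if (length(bad)) {
    stop(sprintf(
      "EffectiveLength must be > 0 when NumReads > 0 (line %d of %s)",
      bad[1L] + 1L, path), call. = FALSE)
  }
  if (anyDuplicated(out$transcript_id)) {
    stop("duplicate transcript id in ", path, ": ",
         out$transcript_id[duplicated(out$transcript_id)][1L], call. = FALSE)
  }
  out
}

#' Write a transcript quantification table
#'
#' Inverse of [read_quant_table()]; writes the Salmon column convention.
#'
#' @param quant A `data.frame` as returned by [read_quant_table()].
#' @param path Output path.
#' @export
write_quant_table <- function(quant, path) {
  out <- data.frame(Name = quant$transcript_id,
                    Length = quant$length,
                    EffectiveLength = quant$effective_length,
                    TPM = quant$tpm,
                    NumReads = quant$num_reads)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples expression matrix from TSV
#'
#' Expects the Trinity matrix dialect: tab-separated, no quoting, first
#' column gene ids, remaining column headers sample ids. Every sample in
#' the header must appear in the sample sheet.
#'
#' @param path Path to the tab-separated matrix.
#' @param sheet A [sample_sheet()] covering every sample column.
#' @param kind Value kind tag for the resulting matrix (the file itself
#'   does not record it); see [count_matrix()].
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, sheet,
                              kind = c("raw", "tpm", "tmm", "log2tmm")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("matrix file needs >= 2 columns", call. = FALSE)
  gene_ids <- as.character(tab[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id in ", path, ": ",
         gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  count_matrix(values, kind = kind, sheet = sheet)
}

#' Write an expression matrix as TSV
#'
#' Writes the Trinity matrix dialect read by [read_count_matrix()].
#' Values round-trip within text precision (15 significant digits).
#'
#' @param cm A [count_matrix()].
#' @param path Output path.
#' @export
write_count_matrix <- function(cm, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(cm$values)), collapse = "\t"), con)
  body <- apply(cm$values, 1L, function(row) {
    paste(as.character(row), collapse = "\t")
  })
  writeLines(paste(rownames(cm$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a gene-to-GO annotation map
#'
#' Two tab-separated columns, `gene_id` and a GO identifier
#' (`GO:` + 7 digits), one pair per line, no header. Duplicate pairs are
#' collapsed; a malformed GO id is an error naming the line.
#'
#' @param path Path to the two-column TSV.
#' @return Named list: gene id -> character vector of unique GO ids.
#' @export
read_gene2go <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    stop("expected 2 tab-separated fields at line ",
         which(nfield != 2L)[1L], " of ", path, call. = FALSE)
  }
  gene <- vapply(parts, `[[`, character(1L), 1L)
  term <- vapply(parts, `[[`, character(1L), 2L)
  bad <- which(!grepl("^GO:[0-9]{7}$", term))
  if (length(bad)) {
    stop(sprintf("malformed GO id '%s' at line %d of %s",
                 term[bad[1L]], bad[1L], path), call. = FALSE)
  }
  lapply(split(term, factor(gene, levels = unique(gene))), unique)
}

#' Write a gene-to-GO annotation map
#'
#' @param gene2go Named list, gene id -> character vector of GO ids.
#' @param path Output path.
#' @export
write_gene2go <- function(gene2go, path) {
  gene <- rep(names(gene2go), lengths(gene2go))
  term <- unlist(gene2go, use.names = FALSE)
  utils::write.table(data.frame(gene, term), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Three tab-separated columns with header: `sample_id`, `tissue`,
#' `replicate`.
#'
#' @param path Path to the TSV.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("sample_id", "tissue", "replicate")
  missing_cols <- setdiff(required, colnames(tab))
  if (length(missing_cols)) {
    stop("sample sheet missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sample_sheet(tab$sample_id, tab$tissue, tab$replicate)
}

#' Remove contaminant contigs from quantification inputs
#'
#' Screens a taxonomy annotation table for contigs whose lineage text
#' contains any of the given keywords (case-insensitive exact token
#' match on whitespace/semicolon/comma-delimited tokens), unions the
#' hits with an explicit exclude list, and removes the matched contigs
#' from every per-sample quantification table and from the
#' transcript-to-gene map. Contigs without an annotation row are kept
#' (only positive keyword hits are treated as contaminants). This step
#' is applied after quantification, before matrix construction.
#'
#' @param quants Named list of per-sample quantification tables (as from
#'   [read_quant_table()]).
#' @param map `data.frame` with columns `transcript_id`, `gene_id`.
#' @param annotations `data.frame` with columns `contig_id`,
#'   `taxonomy_text` (and optionally `uniprot_id`).
#' @param keywords Character vector of taxonomy keywords, e.g.
#'   `c("alveolata", "metazoa", "fungi", "bacteria", "archaea")`.
#' @param extra_exclude Character vector of contig ids to remove
#'   regardless of annotation.
#' @return List with elements `quants`, `map` (both filtered) and
#'   `removed` (character vector of removed contig ids).
#' @export
filter_contaminants <- function(quants, map, annotations, keywords,
                                extra_exclude = character(0)) {
  if (!length(keywords)) stop("keywords must be non-empty", call. = FALSE)
  if (anyDuplicated(annotations$contig_id)) {
    stop("duplicate contig_id in annotation table", call. = FALSE)
  }
  kw <- tolower(keywords)
  tokens <- strsplit(tolower(annotations$taxonomy_text), "[;,[:space:]]+")
  hit <- vapply(tokens, function(tk) any(tk %in% kw), logical(1L))
  removal_set <- union(annotations$contig_id[hit],
                       as.character(extra_exclude))
  present <- unique(c(map$transcript_id,
                      unlist(lapply(quants, `[[`, "transcript_id"),
                             use.names = FALSE)))
  removed <- intersect(removal_set, present)
  quants_f <- lapply(quants, function(q) {
    q[!(q$transcript_id %in% removed), , drop = FALSE]
  })
  map_f <- map[!(map$transcript_id %in% removed), , drop = FALSE]
  rownames(map_f) <- NULL
  list(quants = quants_f, map = map_f, removed = removed)
}
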