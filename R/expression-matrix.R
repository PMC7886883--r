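#' Gene-by-sample expression matrix for one cohort
#'
#' Lightweight container used throughout the pipeline. `values` is a numeric
#' matrix with genes in rows and samples in columns; `scale` records where the
#' matrix sits in the processing chain (`raw_counts` from the sequencer,
#' `log_normalized` after size-factor normalization, `zscored` after per-gene
#' standardization for clustering).
#'
#' @param values numeric matrix, genes x samples.
#' @param cohort_id single string naming the cohort.
#' @param gene_ids,sample_ids character vectors; default to the dimnames of
#'   `values`.
#' @param scale one of `"raw_counts"`, `"log_normalized"`, `"zscored"`.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, cohort_id,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              scale = c("raw_counts", "log_normalized", "zscored")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("gene_ids and sample_ids are required (or set dimnames on `values`)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stopf("values is %d x %d but %d gene ids and %d sample ids were given",
          nrow(values), ncol(values), length(gene_ids), length(sample_ids))
  }
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) stopf("duplicate gene id(s): %s", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) stopf("duplicate sample id(s): %s", paste(unique(dup_s), collapse = ", "))
  if (scale == "raw_counts" && (any(!is.finite(values)) || any(values < 0))) {
    stopf("raw counts must be finite and non-negative")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(cohort_id = as.character(cohort_id)[1], gene_ids = gene_ids,
         sample_ids = sample_ids, values = values, scale = scale),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<ExpressionMatrix> cohort '%s': %d genes x %d samples [%s]\n",
              x$cohort_id, length(x$gene_ids), length(x$sample_ids), x$scale))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene-by-sample expression table
#'
#' Expects a header row, gene identifiers in the first column (`gene_id`) and
#' one column per sample. The delimiter is taken from the file extension
#' (`.csv` comma, anything else tab) unless `delim` overrides it. Row and
#' column order are preserved exactly as on disk.
#'
#' @param path path to a TSV/CSV file.
#' @param cohort_id cohort name recorded on the returned object.
#' @param delim optional delimiter override.
#' @return An `ExpressionMatrix` with `scale = "raw_counts"`.
#' @export
read_expression_matrix <- function(path, cohort_id, delim = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = delim_for(path, delim),
                   check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", quote = "", comment.char = "",
                   fileEncoding = "UTF-8")
  if (ncol(df) < 2) stopf("%s: need a gene id column plus at least one sample", path)
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stopf("%s: duplicate gene id(s): %s", path, paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stopf("%s: duplicate sample id(s): %s", path, paste(unique(dup), collapse = ", "))
  vals <- matrix(NA_real_, nrow(df), length(sample_ids))
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1]]) | is.na(df[[j + 1]]))
    if (length(bad)) {
      stopf("%s: non-numeric value '%s' at row %d (gene %s), column '%s'",
            path, df[[j + 1]][bad[1]], bad[1], gene_ids[bad[1]], sample_ids[j])
    }
    vals[, j] <- v
  }
  expression_matrix(vals, cohort_id, gene_ids, sample_ids, scale = "raw_counts")
}

#' Write an expression matrix to TSV/CSV
#'
#' Inverse of [read_expression_matrix()]: first column `gene_id`, one column
#' per sample, values at full printed precision so a write/read round trip
#' reproduces the object.
#'
#' @param em an `ExpressionMatrix`.
#' @param path output path; extension picks the delimiter unless `delim` set.
#' @param delim optional delimiter override.
#' @export
write_expression_matrix <- function(em, path, delim = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(gene_id = em$gene_ids,
                   format(em$values, trim = TRUE, digits = 15, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", em$sample_ids)
  write.table(df, path, sep = delim_for(path, delim), quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
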