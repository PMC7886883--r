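#' Read per-sample metadata
#'
#' Expects columns `sample_id` and `cohort_id`; any further 0/1 columns are
#' treated as mutation flags (blank or `.` cells mean "unassayed", never 0);
#' optional `os_time` (days) and `os_event` (0/1) carry overall survival.
#'
#' @param path TSV/CSV path (delimiter from extension, see `delim`).
#' @param delim optional delimiter override.
#' @return A data.frame, one row per sample: `sample_id`, `cohort_id`, one
#'   integer column per mutation flag (NA = unassayed), `os_time`, `os_event`.
#' @export
read_sample_metadata <- function(path, delim = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = delim_for(path, delim),
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", ".", "NA"), quote = "",
                   comment.char = "", fileEncoding = "UTF-8")
  need <- c("sample_id", "cohort_id")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$cohort_id <- as.character(df$cohort_id)
  key <- paste(df$cohort_id, df$sample_id)
  if (anyDuplicated(key)) {
    stopf("%s: sample_id duplicated within cohort: %s", path, key[duplicated(key)][1])
  }
  mut_cols <- setdiff(colnames(df), c(need, "os_time", "os_event"))
  for (m in mut_cols) {
    v <- df[[m]]
    if (!all(is.na(v) | v %in% c(0, 1))) stopf("%s: mutation column '%s' must be 0/1/blank", path, m)
    df[[m]] <- as.integer(v)
  }
  if ("os_time" %in% colnames(df)) {
    if (!"os_event" %in% colnames(df)) stopf("%s: os_time present without os_event", path)
    bad <- which(!is.na(df$os_time) & is.na(df$os_event))
    if (length(bad)) stopf("%s: row %d has os_time but no os_event", path, bad[1])
    if (any(df$os_time < 0, na.rm = TRUE)) stopf("%s: negative os_time", path)
    if (!all(is.na(df$os_event) | df$os_event %in% c(0, 1))) stopf("%s: os_event must be 0/1", path)
  } else {
    df$os_time <- NA_real_
    df$os_event <- NA_integer_
  }
  df
}

#' Read a long-format drug screen table
#'
#' Columns: `sample_id`, `drug_id`, `concentration_uM` (> 0), `viability`
#' (fraction of control, >= 0), `replicate` (integer >= 1). Rows need not be
#' sorted; fitting groups them by (sample, drug) downstream.
#'
#' @inheritParams read_sample_metadata
#' @return A data.frame with the five columns above.
#' @export
read_dose_response_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, header = TRUE, sep = delim_for(path, delim),
                   check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", ".", "NA"), quote = "",
                   comment.char = "", fileEncoding = "UTF-8")
  need <- c("sample_id", "drug_id", "concentration_uM", "viability", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df <- df[, need]
  validate_dose_response(df, where = path)
  df
}

validate_dose_response <- function(df, where = "dose-response table") {
  if (any(!is.finite(df$concentration_uM) | df$concentration_uM <= 0)) {
    stopf("%s: concentration_uM must be strictly positive", where)
  }
  if (any(!is.finite(df$viability) | df$viability < 0)) {
    stopf("%s: viability must be >= 0", where)
  }
  if (any(df$replicate < 1 | df$replicate != round(df$replicate))) {
    stopf("%s: replicate must be an integer >= 1", where)
  }
  invisible(df)
}

#' Write a plain data.frame as TSV/CSV
#'
#' Used for all tabular pipeline outputs (subtype assignments, DE tables,
#' drug rankings). Missing values are written as empty cells.
#'
#' @param df a data.frame.
#' @param path output path; extension picks the delimiter unless `delim` set.
#' @param delim optional delimiter override.
#' @export
write_table_out <- function(df, path, delim = NULL) {
  write.table(df, path, sep = delim_for(path, delim), quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
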