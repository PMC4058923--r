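#' Read a gene-by-sample count matrix
#'
#' Reads a delimited text file whose header row holds sample identifiers and
#' whose first column holds gene identifiers, and validates it as a count
#' matrix: every cell must be a non-negative integer and identifiers must be
#' unique. Row and column order are preserved from the file.
#'
#' @param path Path to the file.
#' @param sep Field separator: `"tab"` (default) or `"comma"`.
#' @return A numeric matrix of counts with gene identifiers as row names and
#'   sample identifiers as column names.
#' @seealso [read_sample_sheet()], [write_results()]
#' @export
read_counts <- function(path, sep = c("tab", "comma")) {
  sep <- match.arg(sep)
  delim <- if (sep == "tab") "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("count file must have a gene-id column plus at least one sample")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier: ",
         gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier: ",
         sample_ids[duplicated(sample_ids)][1L])
  mat <- matrix(NA_real_, nrow(raw), length(sample_ids),
                dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(val) | val < 0 | val %% 1 != 0)
    if (length(bad)) {
      i <- bad[1L]
      stop(sprintf("invalid count '%s' at gene '%s', sample '%s'",
                   col[i], gene_ids[i], sample_ids[j]))
    }
    mat[, j] <- val
  }
  mat
}

#' Write a count matrix to a TSV file
#'
#' Inverse of [read_counts()]: writes a header row of sample identifiers and
#' one row per gene, first column `gene_id`.
#'
#' @param counts Validated count matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator, as in [read_counts()].
#' @export
write_counts <- function(counts, path, sep = c("tab", "comma")) {
  sep <- match.arg(sep)
  delim <- if (sep == "tab") "\t" else ","
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet assigns each sequencing library a condition, a replicate
#' (biological culture) and a timepoint in hours. Validation enforces the
#' design assumptions of the model: `(condition, replicate, time_h)` triples
#' are unique, every condition has at least two distinct timepoints, and all
#' replicates within a condition share the same timepoint grid.
#'
#' @param path Path to a delimited file with columns `sample_id`,
#'   `condition`, `replicate`, `time_h`.
#' @param sep Field separator, as in [read_counts()].
#' @return A `data.frame` with the four validated columns; `time_h` numeric.
#' @export
read_sample_sheet <- function(path, sep = c("tab", "comma")) {
  sep <- match.arg(sep)
  delim <- if (sep == "tab") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample-sheet data frame
#'
#' @param df A data frame with columns `sample_id`, `condition`,
#'   `replicate`, `time_h`.
#' @return The validated data frame (with `time_h` coerced to numeric),
#'   invisibly usable as a sample sheet.
#' @export
validate_sample_sheet <- function(df) {
  need <- c("sample_id", "condition", "replicate", "time_h")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols))
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[, need]
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$replicate <- as.character(df$replicate)
  df$time_h <- as.numeric(df$time_h)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L])
  if (any(!is.finite(df$time_h) | df$time_h < 0))
    stop("time_h must be non-negative hours")
  key <- paste(df$condition, df$replicate, df$time_h, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (condition, replicate, time_h): ",
         gsub("\r", "/", key[duplicated(key)][1L]))
  for (cond in unique(df$condition)) {
    sub <- df[df$condition == cond, ]
    times <- sort(unique(sub$time_h))
    if (length(times) < 2L)
      stop("condition '", cond, "' has fewer than 2 distinct timepoints")
    for (rep in unique(sub$replicate)) {
      rt <- sort(sub$time_h[sub$replicate == rep])
      if (!identical(rt, times))
        stop("replicate '", rep, "' in condition '", cond,
             "' does not cover the condition's timepoint grid")
    }
  }
  df
}

#' Check that a count matrix and sample sheet describe the same samples
#'
#' @param counts Count matrix from [read_counts()].
#' @param sheet Sample sheet from [read_sample_sheet()].
#' @return Invisibly, the sheet reordered to the count-matrix column order.
#' @export
check_design <- function(counts, sheet) {
  if (!setequal(colnames(counts), sheet$sample_id) ||
      ncol(counts) != nrow(sheet))
    stop("count matrix columns and sample sheet sample_ids do not match")
  invisible(sheet[match(colnames(counts), sheet$sample_id), ])
}

## Canonical internal sample order: (condition, replicate, time_h).
canonical_order <- function(sheet) {
  order(sheet$condition, sheet$replicate, sheet$time_h)
}

#' Write a differential-dynamics result table
#'
#' Serializes the per-gene results of [dynb_de()] (or any data frame) as TSV
#' with floats kept to 8 significant digits, so a write/read round trip
#' preserves values to at least 6 significant digits.
#'
#' @param table A data frame with at least one row.
#' @param path Output path.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) < 1L)
    stop("result table must contain at least one gene")
  out <- table
  for (j in seq_along(out))
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- signif(out[[j]], 8L)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write results to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back a result table written by [write_results()]
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE)
}
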