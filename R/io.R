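#' Validate a count matrix
#'
#' A count matrix is an ordinary numeric matrix of non-negative integral
#' counts with unique feature row names (miRNAs) and unique sample column
#' names.
#'
#' @param m A matrix.
#' @return `m`, invisibly, if valid; otherwise an error naming the problem.
#' @export
validate_count_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("count matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("count matrix must have feature row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicated feature id(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicated sample id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(m) | m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; first offence at feature '%s', sample '%s'",
      rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  invisible(m)
}

#' Read a count matrix from TSV
#'
#' Tab-separated table; first column holds feature ids, header row holds
#' sample ids. Row and column order is preserved.
#'
#' @param path Path to a TSV file.
#' @return A validated count matrix (features x samples).
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop("malformed count table '", path,
         "': need a feature-id column plus at least one sample column",
         call. = FALSE)
  }
  ids <- as.character(df[[1]])
  sample_ids <- names(df)[-1]       # data-frame subsetting would uniquify
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- sample_ids
  if (!is.numeric(m)) {
    nonnum <- colnames(m)[!vapply(seq_len(ncol(m)),
                                  function(j) is.numeric(df[[j + 1]]),
                                  logical(1))]
    stop("non-numeric count column(s): ", paste(nonnum, collapse = ", "),
         call. = FALSE)
  }
  rownames(m) <- ids
  validate_count_matrix(m)
  m
}

#' Write a count matrix to TSV
#'
#' @param m A count matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  validate_count_matrix(m)
  df <- data.frame(feature_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample table
#'
#' A sample table is a data frame with columns `sample_id`, `subject_id`,
#' `timepoint_h`, `condition` and `dataset_id`. Conditions are limited to
#' `healthy`, `case` and `control`; healthy (time-course) samples must
#' carry a non-negative `timepoint_h` whereas case/control samples may
#' leave it missing, cancer datasets having no time dimension.
#'
#' @param st A data frame.
#' @param counts Optional count matrix whose sample ids must match
#'   `st$sample_id` exactly (each appearing once).
#' @return `st`, invisibly, if valid.
#' @export
validate_sample_table <- function(st, counts = NULL) {
  req <- c("sample_id", "subject_id", "timepoint_h", "condition", "dataset_id")
  if (!is.data.frame(st) || nrow(st) == 0) {
    stop("sample table must be a non-empty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(req, names(st))
  if (length(missing_cols)) {
    stop("sample table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(st$sample_id)) {
    stop("duplicated sample_id(s) in sample table", call. = FALSE)
  }
  allowed <- c("healthy", "case", "control")
  bad <- setdiff(unique(as.character(st$condition)), allowed)
  if (length(bad)) {
    stop("unknown condition value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  tp <- suppressWarnings(as.numeric(st$timepoint_h))
  healthy <- st$condition == "healthy"
  if (any(healthy & is.na(tp))) {
    stop("healthy samples must have timepoint_h set: ",
         paste(st$sample_id[healthy & is.na(tp)], collapse = ", "),
         call. = FALSE)
  }
  if (any(tp < 0, na.rm = TRUE)) {
    stop("timepoint_h must be non-negative", call. = FALSE)
  }
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), st$sample_id) ||
        ncol(counts) != nrow(st)) {
      stop("sample table does not match count matrix samples one-to-one",
           call. = FALSE)
    }
  }
  invisible(st)
}

#' Read a sample table from CSV
#'
#' Expects columns `sample_id, subject_id, timepoint_h, condition,
#' dataset_id`; `timepoint_h` may be empty for case/control samples.
#'
#' @param path Path to a CSV file.
#' @return A validated sample table (data frame).
#' @export
read_sample_table <- function(path) {
  st <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read sample table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(st) == 0) stop("sample table '", path, "' is empty", call. = FALSE)
  st$timepoint_h <- suppressWarnings(as.numeric(st$timepoint_h))
  validate_sample_table(st)
  st
}

#' Write a sample table to CSV
#'
#' @param st A sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(st, path) {
  validate_sample_table(st)
  utils::write.csv(st, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Published seven-miRNA reference panel
#'
#' Loads the packaged transcription of a published pan-cancer reference
#' panel: seven circulating miRNAs with their healthy-blood threshold
#' windows (lower/upper borders of the median +/- 3 x MAD interval of
#' per-timepoint log2 fold changes) and their case/control log2 fold
#' changes across eleven cancer datasets (AML, biliary tract, CLL,
#' colorectal, early colon, gastric, lung adenocarcinoma, nasopharyngeal,
#' pancreatic, prostate cancer and ALL). This fixture drives the worked
#' example: each of the seven miRNAs falls outside its window in at least
#' 9 of the 11 datasets.
#'
#' @param path Path to the TSV; defaults to the copy shipped with the
#'   package.
#' @return A list with elements `windows` (data frame: `feature_id`,
#'   `lower`, `upper`) and `log2fc` (7 x 11 numeric matrix, miRNAs x
#'   datasets).
#' @examples
#' ref <- panel_reference()
#' ref$windows
#' @export
panel_reference <- function(path = system.file("extdata",
                                               "panel_reference_log2fc.tsv",
                                               package = "mirstab")) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  windows <- data.frame(feature_id = df$mirna,
                        lower = df$lower, upper = df$upper,
                        stringsAsFactors = FALSE)
  fc <- as.matrix(df[, setdiff(names(df), c("mirna", "lower", "upper")),
                     drop = FALSE])
  rownames(fc) <- df$mirna
  list(windows = windows, log2fc = fc)
}
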