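#' Construct and validate a feature-by-sample count table
#'
#' A count table is the basic container of the package: a `q x n` matrix of
#' non-negative integer counts with features (OTUs, genes, taxa) in rows and
#' samples in columns, carrying unique feature and sample identifiers as
#' dimnames. All normalization and simulation functions consume and produce
#' this representation.
#'
#' @param counts Numeric matrix (features in rows, samples in columns).
#'   Entries must be non-negative and, unless `allow_real = TRUE`, integral.
#' @param feature_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `counts`; generated as `F1..Fq` / `S1..Sn` when absent.
#' @param allow_real Accept non-negative non-integer entries (for tables
#'   that have already been normalized). Such tables are rejected by the
#'   simulators, which require raw counts.
#' @return A validated integer-valued matrix of class `count_table`.
#' @examples
#' tab <- count_table(matrix(c(1, 2, 3, 4), 2, 2))
#' ncol(tab)
#' @export
count_table <- function(counts, feature_ids = NULL, sample_ids = NULL,
                        allow_real = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (!is.null(feature_ids)) rownames(counts) <- feature_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  if (is.null(rownames(counts)) && nrow(counts) > 0L)
    rownames(counts) <- paste0("F", seq_len(nrow(counts)))
  if (is.null(colnames(counts)) && ncol(counts) > 0L)
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  structure(counts, class = c("count_table", "matrix", "array")) |>
    validate_count_table(allow_real = allow_real)
}

#' @rdname count_table
#' @param x Object to validate.
#' @export
validate_count_table <- function(x, allow_real = FALSE) {
  if (!is.matrix(x)) stop("count table must be a matrix")
  if (nrow(x) < 1L) stop("count table must have at least one feature (q >= 1)")
  if (ncol(x) < 1L) stop("count table must have at least one sample")
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative count at feature '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  if (!allow_real && any(x != round(x))) {
    bad <- which(x != round(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integer count at feature '%s', sample '%s'",
                 rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
  }
  if (anyDuplicated(rownames(x))) stop("duplicate feature identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  x
}

#' Read a count table from delimited text or a matrix-market triplet file
#'
#' The dense dialect is features-in-rows with a header row of sample
#' identifiers and feature identifiers in the first column (the dominant
#' OTU-table convention). The sparse dialect is a matrix-market coordinate
#' file accompanied by two plain-text identifier files.
#'
#' @param path Path to the table.
#' @param fmt One of `"tsv"`, `"csv"`, `"mtx"`. Guessed from the file
#'   extension when missing.
#' @param samples_in_rows For dense input, transpose after reading.
#' @param feature_path,sample_path For `fmt = "mtx"`, paths of the row and
#'   column identifier files (one id per line); default `<path>.features`
#'   and `<path>.samples`.
#' @param allow_real Accept non-integer non-negative entries.
#' @return A `count_table`.
#' @seealso [write_count_table()]
#' @export
read_count_table <- function(path, fmt = c("tsv", "csv", "mtx"),
                             samples_in_rows = FALSE,
                             feature_path = paste0(path, ".features"),
                             sample_path = paste0(path, ".samples"),
                             allow_real = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(fmt)) {
    fmt <- switch(tolower(tools::file_ext(path)),
                  csv = "csv", mtx = "mtx", "tsv")
  }
  fmt <- match.arg(fmt)
  if (fmt == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(feature_path)
    cn <- readLines(sample_path)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("identifier files do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
    return(count_table(m, allow_real = allow_real))
  }
  sep <- if (fmt == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, comment.char = "",
                          quote = "\"", na.strings = "NA")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in count table")
  if (samples_in_rows) m <- t(m)
  count_table(m, allow_real = allow_real)
}

#' Write a count table
#'
#' Inverse of [read_count_table()]: a written table reads back identically.
#'
#' @inheritParams read_count_table
#' @param table A `count_table`.
#' @export
write_count_table <- function(table, path, fmt = c("tsv", "csv", "mtx"),
                              feature_path = paste0(path, ".features"),
                              sample_path = paste0(path, ".samples")) {
  table <- validate_count_table(table, allow_real = TRUE)
  fmt <- match.arg(fmt)
  if (fmt == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unclass(table), sparse = TRUE), path)
    writeLines(rownames(table), feature_path)
    writeLines(colnames(table), sample_path)
    return(invisible(path))
  }
  sep <- if (fmt == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("feature_id", colnames(table)), collapse = sep), con)
  utils::write.table(unclass(table), con, sep = sep, col.names = FALSE,
                     row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read sample labels
#'
#' Two-column delimited text: sample identifier and group (or subject)
#' label, with or without a header line.
#'
#' @param path Path to the label file.
#' @param table Optional `count_table`; when given, labels are checked to
#'   match its samples one-to-one and reordered to the table's column order.
#' @return A data.frame with columns `sample_id` and `group`.
#' @export
read_sample_labels <- function(path, table = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample_id", "group"),
                          colClasses = "character")
  if (identical(tolower(df$sample_id[1L]), "sample_id")) df <- df[-1L, ]
  rownames(df) <- NULL
  if (!is.null(table)) {
    if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in labels")
    miss <- setdiff(colnames(table), df$sample_id)
    if (length(miss))
      stop("labels missing for samples: ", paste(miss, collapse = ", "))
    df <- df[match(colnames(table), df$sample_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Divide counts by per-sample size factors
#'
#' Produces the normalized abundance matrix: entry `(k, i)` is
#' `c_ki / s_i`. Zeros remain zeros.
#'
#' @param table A `count_table`.
#' @param sf A [size_factors] object (or named positive numeric vector)
#'   aligned to the samples of `table`.
#' @return A `q x n` numeric matrix of normalized abundances.
#' @export
normalize_counts <- function(table, sf) {
  table <- validate_count_table(table, allow_real = TRUE)
  v <- as.numeric(sf)
  ids <- names(sf) %||% attr(sf, "sample_ids")
  if (is.null(ids)) stop("size factors carry no sample ids")
  if (!setequal(ids, colnames(table)) || length(ids) != ncol(table))
    stop("size factors are not aligned with the table's samples")
  v <- v[match(colnames(table), ids)]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all size factors must be positive and finite")
  sweep(unclass(table), 2L, v, "/")
}
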