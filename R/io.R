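#' Read a raw count matrix
#'
#' Reads a gene-by-sample count table from delimited text (first column
#' `gene_id`, one column per sample) or MatrixMarket coordinate format with
#' `genes.txt`/`samples.txt` sidecar files (one identifier per line).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param genes_file,samples_file sidecar identifier files for MTX input;
#'   default `genes.txt` and `samples.txt` next to `path`.
#' @return A raw [count_matrix()]. Non-integer entries warn but do not fail.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        genes_file = NULL, samples_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    dir <- dirname(path)
    genes_file <- genes_file %||% file.path(dir, "genes.txt")
    samples_file <- samples_file %||% file.path(dir, "samples.txt")
    m <- as.matrix(Matrix::readMM(path))
    gn <- readLines(genes_file)
    sn <- readLines(samples_file)
    if (length(gn) != nrow(m)) stop("genes sidecar length does not match matrix rows")
    if (length(sn) != ncol(m)) stop("samples sidecar length does not match matrix columns")
    dimnames(m) <- list(gn, sn)
  } else {
    df <- if (format == "csv") {
      read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    }
    if (ncol(df) < 3L) stop("malformed count table: need gene id column plus >= 2 samples")
    gn <- as.character(df[[1L]])
    if (anyDuplicated(gn)) {
      stop("duplicated gene ids: ", paste(unique(gn[duplicated(gn)]), collapse = ", "))
    }
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("malformed count table: non-numeric entries")
    rownames(m) <- gn
  }
  count_matrix(m, is_raw = TRUE)
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; `read -> write -> read` reproduces integer
#' matrices exactly in every format.
#'
#' @param x a [count_matrix()] or matrix.
#' @param path output file path.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("auto", "tsv", "csv", "mtx"),
                         genes_file = NULL, samples_file = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  m <- count_values(x)
  if (format == "mtx") {
    dir <- dirname(path)
    genes_file <- genes_file %||% file.path(dir, "genes.txt")
    samples_file <- samples_file %||% file.path(dir, "samples.txt")
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), genes_file)
    writeLines(colnames(m), samples_file)
  } else {
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (format == "csv") {
      write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
      write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' Read a sample design table
#'
#' Reads per-sample metadata from TSV/CSV. The condition column must have
#' exactly two observed levels; their order of first appearance defines the
#' reference level (the condition coefficient is level 2 minus level 1 on the
#' log scale). Gene/sample identifier matching everywhere is exact and
#' case-sensitive.
#'
#' @param path TSV or CSV file with a `sample_id` column.
#' @param condition_col name of the condition column.
#' @param random_cols character vector of random-effect grouping columns.
#' @return A `DesignTable` (see [design_table()]).
#' @export
read_design <- function(path, condition_col = "condition",
                        random_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  make_design(df, condition_col = condition_col, random_cols = random_cols)
}
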