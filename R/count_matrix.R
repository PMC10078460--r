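#' Gene-by-sample count matrix
#'
#' Lightweight container for an RNA-seq count table: a numeric matrix whose
#' rows are genes and columns are samples, plus a flag recording whether the
#' values are raw read counts or have been scale-corrected/normalized.
#'
#' @param values numeric matrix (or object coercible to one) with unique,
#'   non-empty rownames (gene identifiers) and colnames (sample identifiers).
#' @param is_raw logical; `TRUE` for raw read counts. Non-integer entries in a
#'   raw matrix trigger a warning (expected counts from some quantifiers), not
#'   an error.
#'
#' @return An object of class `CountMatrix`: a list with elements `values`
#'   (the matrix) and `is_raw`.
#' @export
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' count_matrix(m)
count_matrix <- function(values, is_raw = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_count_values(values, is_raw = is_raw)
  structure(list(values = values, is_raw = isTRUE(is_raw)), class = "CountMatrix")
}

validate_count_values <- function(values, is_raw = TRUE) {
  if (nrow(values) < 1L) stop("count matrix must have at least one gene")
  if (ncol(values) < 2L) stop("count matrix must have at least two samples")
  gn <- rownames(values)
  sn <- colnames(values)
  if (is.null(gn) || any(!nzchar(gn))) stop("gene identifiers (rownames) are required")
  if (is.null(sn) || any(!nzchar(sn))) stop("sample identifiers (colnames) are required")
  if (anyDuplicated(gn)) {
    stop("duplicated gene ids: ", paste(unique(gn[duplicated(gn)]), collapse = ", "))
  }
  if (anyDuplicated(sn)) {
    stop("duplicated sample ids: ", paste(unique(sn[duplicated(sn)]), collapse = ", "))
  }
  if (anyNA(values)) stop("count matrix contains missing values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative entry at gene '%s', sample '%s'",
                 gn[neg[1, 1]], sn[neg[1, 2]]))
  }
  if (isTRUE(is_raw) && any(values != floor(values))) {
    warning("raw count matrix contains non-integer entries; ",
            "expected raw read counts")
  }
  invisible(values)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$is_raw) "raw counts" else "corrected/normalized"))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' Gene and sample identifiers of a CountMatrix
#' @param x a [count_matrix()] object.
#' @return Character vector of identifiers.
#' @export
genes <- function(x) rownames(count_values(x))

#' @rdname genes
#' @export
samples <- function(x) colnames(count_values(x))

# Accept either a CountMatrix or a plain named matrix everywhere.
count_values <- function(x) {
  if (inherits(x, "CountMatrix")) return(x$values)
  if (is.matrix(x)) return(x)
  stop("expected a CountMatrix or a matrix")
}

as_count_matrix <- function(x, is_raw = TRUE) {
  if (inherits(x, "CountMatrix")) return(x)
  count_matrix(x, is_raw = is_raw)
}

#' Per-sample design table
#'
#' Builds the sample metadata table used throughout the pipeline: one row per
#' sample, a condition factor with exactly two levels (pairwise designs), and
#' zero or more random-effect grouping columns. The reference condition level
#' is the level appearing first in the table; fitted condition coefficients
#' are second level minus reference on the natural-log scale.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param condition vector with exactly two distinct values; coerced to a
#'   factor whose level order is order of first appearance.
#' @param ... optional named random-effect grouping columns (e.g. `gender =`),
#'   each one value per sample.
#'
#' @return A `DesignTable` data frame with attributes `condition_col`
#'   (`"condition"`) and `random_cols`.
#' @export
design_table <- function(sample_id, condition, ...) {
  extra <- list(...)
  df <- data.frame(sample_id = as.character(sample_id),
                   condition = as.character(condition),
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  make_design(df, condition_col = "condition",
              random_cols = names(extra) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_design <- function(df, condition_col, random_cols = character()) {
  if (!"sample_id" %in% names(df)) stop("design requires a 'sample_id' column")
  if (!condition_col %in% names(df)) {
    stop("condition column '", condition_col, "' not found in design")
  }
  missing_rc <- setdiff(random_cols, names(df))
  if (length(missing_rc)) {
    stop("random-effect column(s) not found in design: ",
         paste(missing_rc, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample ids in design: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  cond <- as.character(df[[condition_col]])
  lev <- unique(cond)
  if (length(lev) != 2L) {
    stop("pairwise mode requires exactly 2 condition levels, found ",
         length(lev), " (", paste(lev, collapse = ", "), ")")
  }
  if (any(table(cond) < 2L)) {
    stop("each condition level needs at least 2 biological replicates")
  }
  df[[condition_col]] <- factor(cond, levels = lev)
  for (rc in random_cols) df[[rc]] <- factor(as.character(df[[rc]]))
  structure(df,
            condition_col = condition_col,
            random_cols = as.character(random_cols),
            class = c("DesignTable", "data.frame"))
}

design_condition <- function(design) {
  design[[attr(design, "condition_col") %||% "condition"]]
}

#' Align a count matrix with its design table
#'
#' Reorders the matrix columns to the design row order and checks that the
#' two objects describe exactly the same samples. Idempotent.
#'
#' @param x a [count_matrix()].
#' @param design a [design_table()] covering all matrix samples.
#' @return A list with elements `matrix` and `design`, consistent and in
#'   design row order.
#' @export
align_counts <- function(x, design) {
  x <- as_count_matrix(x, is_raw = TRUE)
  sm <- samples(x)
  sd_ <- design$sample_id
  miss <- setdiff(sd_, sm)
  if (length(miss)) {
    stop("design sample(s) missing from count matrix: ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(sm, sd_)
  if (length(extra)) {
    stop("count matrix sample(s) missing from design: ",
         paste(extra, collapse = ", "))
  }
  x$values <- x$values[, sd_, drop = FALSE]
  list(matrix = x, design = design)
}
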