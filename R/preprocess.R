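#' Preprocessing configuration
#'
#' @param wilcoxon_alpha significance level for the zero-comparison Wilcoxon
#'   filter applied to partially expressed genes (default 0.05).
#' @param cpm_threshold average counts-per-million cutoff; genes at or below
#'   it are removed (default 1).
#' @param run_scale_correction,run_rle logical switches for the scale
#'   correction and relative-log-expression normalization stages.
#' @return A `PreprocessConfig` list.
#' @export
preprocess_config <- function(wilcoxon_alpha = 0.05, cpm_threshold = 1,
                              run_scale_correction = TRUE, run_rle = TRUE) {
  if (!(wilcoxon_alpha > 0 && wilcoxon_alpha < 1)) {
    stop("wilcoxon_alpha must be in (0, 1)")
  }
  if (cpm_threshold < 0) stop("cpm_threshold must be >= 0")
  structure(list(wilcoxon_alpha = wilcoxon_alpha,
                 cpm_threshold = cpm_threshold,
                 run_scale_correction = isTRUE(run_scale_correction),
                 run_rle = isTRUE(run_rle)),
            class = "PreprocessConfig")
}

#' Library scale correction
#'
#' Rescales every library (column) to the smallest library size: with column
#' sums \eqn{\nu_j} and \eqn{\lambda = \min_j \nu_j}, each entry becomes
#' \eqn{a^*_{ij} = (\lambda/\nu_j)\, a_{ij}}, so all corrected column sums
#' equal \eqn{\lambda}.
#'
#' @param x a [count_matrix()] or matrix.
#' @return A list with `matrix` (corrected `CountMatrix`, `is_raw = FALSE`),
#'   `lambda`, and `nu` (the input column sums).
#' @export
scale_correct <- function(x) {
  m <- count_values(x)
  nu <- colSums(m)
  if (any(nu <= 0)) {
    stop("library with zero total counts: ",
         paste(colnames(m)[nu <= 0], collapse = ", "))
  }
  lambda <- min(nu)
  out <- sweep(m, 2L, lambda / nu, "*")
  list(matrix = structure(list(values = out, is_raw = FALSE),
                          class = "CountMatrix"),
       lambda = lambda, nu = nu)
}

#' Relative-log-expression size factors
#'
#' Median-of-ratios size factors: each sample's factor is the median, over
#' genes with strictly positive counts in all samples, of the gene count
#' divided by the gene's geometric mean across samples.
#'
#' @param x a [count_matrix()] or matrix.
#' @return Named numeric vector of positive size factors.
#' @export
rle_size_factors <- function(x) {
  m <- count_values(x)
  ref <- rowSums(m <= 0) == 0L
  if (!any(ref)) stop("RLE undefined: no gene with all-positive counts")
  logm <- log(m[ref, , drop = FALSE])
  geo <- rowMeans(logm)
  sf <- apply(exp(logm - geo), 2L, median)
  if (any(sf <= 0)) stop("RLE produced a non-positive size factor")
  sf
}

#' Remove genes with zero counts in every sample
#'
#' @param x a [count_matrix()] or matrix.
#' @return List with `matrix` (retained rows) and `removed` (gene ids).
#' @export
filter_all_zero <- function(x) {
  cm <- as_filter_input(x)
  keep <- rowSums(cm$values > 0) > 0L
  filter_result(cm, keep)
}

#' Wilcoxon filter for partially expressed genes
#'
#' Genes expressed in some but not all samples are compared against an
#' all-zero vector of the same length with a two-sided Mann-Whitney rank-sum
#' test (exact permutation enumeration for n <= 8 samples, tie-corrected
#' normal approximation with continuity correction otherwise). Tested genes
#' are kept only when P < `alpha`; genes positive in every sample bypass the
#' test.
#'
#' @param x a [count_matrix()] or matrix (no all-zero rows expected; apply
#'   [filter_all_zero()] first).
#' @param alpha significance level (default 0.05).
#' @return List with `matrix`, `removed`, and `kept_partial` (tested genes
#'   that passed and are grouped with the fully expressed ones).
#' @export
filter_partial_wilcoxon <- function(x, alpha = 0.05) {
  cm <- as_filter_input(x)
  m <- cm$values
  has_zero <- rowSums(m == 0) > 0L
  has_pos <- rowSums(m > 0) > 0L
  tested <- has_zero & has_pos
  keep <- !has_zero | !has_pos  # untested genes pass through
  kept_partial <- character()
  if (any(tested)) {
    cache <- new.env(parent = emptyenv())
    pvals <- apply(m[tested, , drop = FALSE], 1L, zero_wilcoxon_pvalue,
                   cache = cache)
    keep[tested] <- pvals < alpha
    kept_partial <- rownames(m)[tested][pvals < alpha]
  }
  out <- filter_result(cm, keep)
  out$kept_partial <- kept_partial
  out
}

#' Two-sided rank-sum P-value of counts against an all-zero vector
#'
#' The building block of [filter_partial_wilcoxon()]: a Mann-Whitney test of
#' the gene's pooled count vector versus a zero vector of equal length. For
#' n <= 8 the exact permutation distribution of the rank sum is enumerated
#' over all splits of the combined sample; for larger n the tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param y non-negative numeric vector of counts.
#' @param cache optional environment memoizing exact null distributions
#'   across calls (they depend only on the tie structure).
#' @return Two-sided P-value in `[0, 1]`.
#' @export
zero_wilcoxon_pvalue <- function(y, cache = NULL) {
  n <- length(y)
  combined <- c(y, rep(0, n))
  r <- rank(combined)
  W <- sum(r[seq_len(n)])
  EW <- n * (2 * n + 1) / 2
  if (n <= 8L) {
    key <- paste(signif(sort(r), 12), collapse = ",")
    dist <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(dist)) {
      idx <- combn(2L * n, n)
      dist <- colSums(matrix(r[idx], nrow = n))
      if (!is.null(cache)) cache[[key]] <- dist
    }
    p <- mean(abs(dist - EW) >= abs(W - EW) - 1e-9)
  } else {
    N <- 2L * n
    t <- table(combined)
    s2 <- (n * n / 12) * ((N + 1) - sum(t^3 - t) / (N * (N - 1)))
    if (s2 <= 0) return(1)
    z <- max(0, abs(W - EW) - 0.5) / sqrt(s2)
    p <- min(1, 2 * pnorm(-z))
  }
  p
}

#' Remove genes with identical counts in every sample
#'
#' Operates on raw integer counts (exact equality), since library-size
#' division destroys equality of read numbers.
#'
#' @param x a [count_matrix()] or matrix of raw counts.
#' @return List with `matrix` and `removed`.
#' @export
filter_constant <- function(x) {
  cm <- as_filter_input(x)
  m <- cm$values
  keep <- matrixStats_row_distinct(m) >= 2L
  filter_result(cm, keep)
}

# number of distinct values per row, without extra dependencies
matrixStats_row_distinct <- function(m) {
  apply(m, 1L, function(v) length(unique(v)))
}

#' Remove genes with low average counts per million
#'
#' CPM is computed against the raw (pre-correction) library sizes; a gene is
#' removed when its mean CPM over samples is at or below `threshold`.
#'
#' @param x a [count_matrix()] or matrix of raw counts for the surviving
#'   genes.
#' @param raw_libsizes positive per-sample library sizes from the unfiltered
#'   raw matrix.
#' @param threshold average-CPM cutoff (default 1).
#' @return List with `matrix` and `removed`.
#' @export
filter_low_cpm <- function(x, raw_libsizes, threshold = 1) {
  cm <- as_filter_input(x)
  m <- cm$values
  if (length(raw_libsizes) != ncol(m)) {
    stop("raw_libsizes length must match the number of samples")
  }
  if (any(raw_libsizes <= 0)) stop("raw library sizes must be positive")
  cpm <- sweep(m, 2L, raw_libsizes, "/") * 1e6
  keep <- rowMeans(cpm) > threshold
  filter_result(cm, keep)
}

as_filter_input <- function(x) {
  if (inherits(x, "CountMatrix")) x else
    structure(list(values = count_values(x), is_raw = TRUE),
              class = "CountMatrix")
}

filter_result <- function(cm, keep) {
  removed <- rownames(cm$values)[!keep]
  cm$values <- cm$values[keep, , drop = FALSE]
  list(matrix = cm, removed = removed)
}

#' Preprocess a raw count matrix
#'
#' Runs the full preprocessing pipeline in fixed order: scale correction,
#' relative-log-expression normalization, then four filtering stages on the
#' raw counts — all-zero genes, partially expressed genes failing the
#' zero-comparison Wilcoxon test, constant genes, and low-CPM genes. Each
#' removed gene is attributed to the first stage that removes it, so the
#' per-stage tallies partition the input gene set.
#'
#' @param x raw [count_matrix()].
#' @param design matching [design_table()]; columns are aligned to it.
#' @param config a [preprocess_config()].
#' @param truth optional ground-truth labels (data frame with `gene_id` and
#'   `label` in `up`/`down`/`non-DEG`, as produced by [simulate_fixed()]);
#'   when given, the report includes the percentage of true DEGs removed.
#' @return A `preprocessed_counts` object: `counts` (raw counts of retained
#'   genes), `normalized` (scale-corrected, RLE-normalized retained matrix),
#'   `design`, and `report` with stage tallies, removed-id lists, size
#'   factors, raw library sizes and optional `deg_loss_percent`.
#' @export
preprocess <- function(x, design, config = preprocess_config(), truth = NULL) {
  al <- align_counts(x, design)
  x <- al$matrix
  design <- al$design
  raw <- x$values
  n_input <- nrow(raw)
  nu <- colSums(raw)
  if (any(nu <= 0)) {
    stop("library with zero total counts: ",
         paste(colnames(raw)[nu <= 0], collapse = ", "))
  }

  corrected <- if (config$run_scale_correction) scale_correct(x)$matrix$values
               else raw
  sf <- if (config$run_rle) rle_size_factors(corrected)
        else stats::setNames(rep(1, ncol(raw)), colnames(raw))
  normalized <- sweep(corrected, 2L, sf, "/")

  n_expressed_all <- sum(rowSums(raw > 0) == ncol(raw))

  s1 <- filter_all_zero(raw)
  s2 <- filter_partial_wilcoxon(s1$matrix, alpha = config$wilcoxon_alpha)
  s3 <- filter_constant(s2$matrix)
  s4 <- filter_low_cpm(s3$matrix, raw_libsizes = nu,
                       threshold = config$cpm_threshold)

  retained_ids <- rownames(s4$matrix$values)
  removed_ids <- list(all_zero = s1$removed,
                      partial_wilcoxon = s2$removed,
                      constant = s3$removed,
                      low_cpm = s4$removed)

  deg_loss_percent <- NULL
  if (!is.null(truth)) {
    truth <- normalize_truth(truth)
    deg_ids <- truth$gene_id[truth$label != "non-DEG"]
    deg_ids <- intersect(deg_ids, rownames(raw))
    if (length(deg_ids)) {
      lost <- setdiff(deg_ids, retained_ids)
      deg_loss_percent <- 100 * length(lost) / length(deg_ids)
    } else {
      deg_loss_percent <- 0
    }
  }

  report <- structure(list(
    n_input_genes = n_input,
    n_expressed_all_replicates = n_expressed_all,
    n_unexpressed = length(s1$removed),
    n_partial_removed = length(s2$removed),
    n_partial_kept = length(s2$kept_partial),
    n_constant_removed = length(s3$removed),
    n_lowcpm_removed = length(s4$removed),
    n_retained = length(retained_ids),
    removed_ids = removed_ids,
    kept_partial_ids = s2$kept_partial,
    size_factors = sf,
    raw_libsizes = nu,
    lambda = min(nu),
    deg_loss_percent = deg_loss_percent
  ), class = "PreprocessReport")

  structure(list(
    counts = count_matrix(raw[retained_ids, , drop = FALSE], is_raw = TRUE),
    normalized = structure(list(values = normalized[retained_ids, , drop = FALSE],
                                is_raw = FALSE), class = "CountMatrix"),
    design = design,
    report = report
  ), class = "preprocessed_counts")
}

normalize_truth <- function(truth) {
  if (is.data.frame(truth)) {
    stopifnot(all(c("gene_id", "label") %in% names(truth)))
    data.frame(gene_id = as.character(truth$gene_id),
               label = as.character(truth$label),
               stringsAsFactors = FALSE)
  } else {
    stop("truth must be a data frame with gene_id and label columns")
  }
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat("Preprocessing report\n")
  cat(sprintf("  input genes:              %d\n", x$n_input_genes))
  cat(sprintf("  expressed in all samples: %d\n", x$n_expressed_all_replicates))
  cat(sprintf("  removed, all-zero:        %d\n", x$n_unexpressed))
  cat(sprintf("  removed, Wilcoxon:        %d (kept partial: %d)\n",
              x$n_partial_removed, x$n_partial_kept))
  cat(sprintf("  removed, constant:        %d\n", x$n_constant_removed))
  cat(sprintf("  removed, low CPM:         %d\n", x$n_lowcpm_removed))
  cat(sprintf("  retained:                 %d\n", x$n_retained))
  if (!is.null(x$deg_loss_percent)) {
    cat(sprintf("  true DEGs lost:           %.2f%%\n", x$deg_loss_percent))
  }
  invisible(x)
}

#' @export
print.preprocessed_counts <- function(x, ...) {
  print(x$report)
  invisible(x)
}
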