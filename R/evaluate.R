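#' Confusion counts of a DEG call set against simulation truth
#'
#' Scores a set of called genes against ground-truth labels. Calls must be a
#' subset of the truth gene universe; genes that were filtered out upstream
#' simply do not appear among the calls and are scored as negatives, so
#' preprocessing loss of true DEGs materializes as false negatives.
#'
#' @param truth data frame with `gene_id` and `label` (`up`/`down`/`non-DEG`),
#'   as produced by [simulate_fixed()].
#' @param calls character vector of gene ids called differentially expressed,
#'   or a data frame with `gene_id` and logical/yes-no `significant`.
#' @return A `ConfusionCounts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, calls) {
  truth <- normalize_truth(truth)
  if (is.data.frame(calls)) {
    stopifnot(all(c("gene_id", "significant") %in% names(calls)))
    sig <- calls$significant
    if (!is.logical(sig)) sig <- tolower(as.character(sig)) %in% c("yes", "true", "1")
    calls <- as.character(calls$gene_id[sig])
  }
  calls <- unique(as.character(calls))
  extra <- setdiff(calls, truth$gene_id)
  if (length(extra)) {
    stop("calls contain ", length(extra),
         " gene id(s) outside the truth universe")
  }
  is_deg <- truth$label != "non-DEG"
  called <- truth$gene_id %in% calls
  structure(list(tp = sum(is_deg & called), fp = sum(!is_deg & called),
                 tn = sum(!is_deg & !called), fn = sum(is_deg & !called)),
            class = "ConfusionCounts")
}

#' Precision, recall and accuracy
#'
#' With no positive calls, precision is reported as 1 when there are also no
#' true DEGs to find, and 0 otherwise.
#'
#' @param cc a [confusion()] result.
#' @return List with `precision`, `recall`, `accuracy`.
#' @export
de_metrics <- function(cc) {
  stopifnot(inherits(cc, "ConfusionCounts"))
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  precision <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp)
               else if (cc$fn == 0) 1 else 0
  recall <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else 1
  list(precision = precision, recall = recall,
       accuracy = (cc$tp + cc$tn) / total)
}

#' Read an external caller's output for scoring
#'
#' Accepts a two-column TSV (`gene_id`, `significant` as yes/no, true/false
#' or 0/1) so results from any differential-expression tool can be scored
#' side by side with [confusion()].
#'
#' @param path TSV file path.
#' @return Character vector of significant gene ids.
#' @export
read_calls <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "significant") %in% names(df)))
  sig <- tolower(as.character(df$significant)) %in% c("yes", "true", "1")
  as.character(df$gene_id[sig])
}

#' Built-in DEG callers for benchmarking
#'
#' `call_mixedde()` runs preprocessing followed by the NB GLMM with a
#' per-sample random intercept; `call_nbglm()` is the fixed-effects NB GLM
#' baseline through the identical preprocessing. Both return the significant
#' gene ids at the chosen correction and level.
#'
#' @param counts raw [count_matrix()].
#' @param design matching [design_table()].
#' @param correction `"BH"` or `"bonferroni"`.
#' @param alpha significance level on adjusted p-values.
#' @param lfc_cutoff minimum |log2FC| called.
#' @return Character vector of called gene ids.
#' @export
call_mixedde <- function(counts, design, correction = "BH", alpha = 0.05,
                         lfc_cutoff = 0) {
  pp <- preprocess(counts, design)
  res <- run_inference(pp, random = "sample_id", correction = correction,
                       alpha = alpha, lfc_cutoff = lfc_cutoff)
  res$gene_id[res$direction != "ns"]
}

#' @rdname call_mixedde
#' @export
call_nbglm <- function(counts, design, correction = "BH", alpha = 0.05,
                       lfc_cutoff = 0) {
  pp <- preprocess(counts, design)
  res <- run_inference(pp, random = NULL, correction = correction,
                       alpha = alpha, lfc_cutoff = lfc_cutoff)
  res$gene_id[res$direction != "ns"]
}

#' Benchmark grid runner
#'
#' Simulates one dataset per grid cell and seed (optionally injecting random
#' effects when `sdnd > 0`, using the replicate-matched default mean), runs
#' every caller on it, and scores precision, recall and accuracy against the
#' simulation truth. A caller failure yields a row of `NA` metrics and the
#' run continues.
#'
#' @param grid data frame with columns `replicates`, `deg_proportion`,
#'   `sdnd` (0 for fixed effects only).
#' @param methods named list of caller functions `f(counts, design)`
#'   returning called gene ids, e.g. [call_mixedde()].
#' @param seeds integer vector of simulation seeds.
#' @param n_genes genes per simulated matrix (default 5000).
#' @param ... further arguments passed to [sim_config()].
#' @return Data frame with one row per (cell, method, seed): the grid cell,
#'   `method`, `seed`, `precision`, `recall`, `accuracy`.
#' @export
benchmark_grid <- function(grid, methods, seeds = 1L, n_genes = 5000L, ...) {
  stopifnot(is.data.frame(grid),
            all(c("replicates", "deg_proportion", "sdnd") %in% names(grid)),
            length(names(methods)) == length(methods))
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    for (seed in seeds) {
      sim <- simulate_fixed(sim_config(n_genes = n_genes,
                                       replicates = cell$replicates,
                                       deg_proportion = cell$deg_proportion,
                                       seed = seed, ...))
      counts <- sim$matrix
      if (cell$sdnd > 0) {
        counts <- inject_random_effects(
          counts, re_config(mean = default_re_mean(cell$replicates),
                            sdnd = cell$sdnd, seed = seed + 70001L))
      }
      for (mname in names(methods)) {
        met <- tryCatch({
          calls <- methods[[mname]](counts, sim$design)
          de_metrics(confusion(sim$truth, calls))
        }, error = function(e) {
          warning("method '", mname, "' failed on cell ", ci, ", seed ", seed,
                  ": ", conditionMessage(e))
          list(precision = NA_real_, recall = NA_real_, accuracy = NA_real_)
        })
        rows[[length(rows) + 1L]] <- data.frame(
          replicates = cell$replicates, deg_proportion = cell$deg_proportion,
          sdnd = cell$sdnd, method = mname, seed = seed,
          precision = met$precision, recall = met$recall,
          accuracy = met$accuracy, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
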